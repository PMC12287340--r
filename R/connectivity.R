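#' Connectivity specification for a rate network
#'
#' Describes how the four weight structures of the network are drawn:
#' the fixed chaotic matrix `G` (sparse, strong), the plastic matrix `M`
#' (dense, initially weak), the readout `W`, the random feedback `Q` and
#' the optional input weights `W_in`.  Entries of `G` and `M` are Gaussian
#' with standard deviation `g / sqrt(p * N)` on a Bernoulli(`p`) mask, so
#' a gain `g > 1` for `G` produces chaotic spontaneous activity.
#'
#' Defaults follow the standard rate-network setting `(p, g) = (0.1, 1.2)`
#' for `G` and `(1.0, 0.5)` for `M`.
#'
#' @param N number of recurrent units.
#' @param p_g,g_g connection probability and gain of the fixed matrix `G`.
#' @param p_m,g_m connection probability and gain of the plastic matrix `M`.
#' @param K number of readout units.
#' @param n_in number of input channels (0 for autonomous tasks).
#' @param seed RNG seed used by [init_connectivity()].
#' @return An object of class `connectivity_spec`.
#' @examples
#' spec <- connectivity_spec(N = 100, seed = 1)
#' conn <- init_connectivity(spec)
#' @export
connectivity_spec <- function(N = 500, p_g = 0.1, g_g = 1.2,
                              p_m = 1.0, g_m = 0.5,
                              K = 1, n_in = 0, seed = 1L) {
  if (N < 1) stop("N must be >= 1")
  if (p_g <= 0 || p_g > 1) stop("p_g must lie in (0, 1]")
  if (p_m <= 0 || p_m > 1) stop("p_m must lie in (0, 1]")
  if (g_g < 0 || g_m < 0) stop("gains g_g and g_m must be >= 0")
  if (K < 1) stop("K must be >= 1")
  if (n_in < 0) stop("n_in must be >= 0")
  structure(
    list(N = as.integer(N), p_g = p_g, g_g = g_g, p_m = p_m, g_m = g_m,
         K = as.integer(K), n_in = as.integer(n_in), seed = as.integer(seed)),
    class = "connectivity_spec")
}

#' @export
print.connectivity_spec <- function(x, ...) {
  cat(sprintf(
    "connectivity_spec: N=%d, G(p=%.3g, g=%.3g), M(p=%.3g, g=%.3g), K=%d, n_in=%d, seed=%d\n",
    x$N, x$p_g, x$g_g, x$p_m, x$g_m, x$K, x$n_in, x$seed))
  invisible(x)
}

draw_sparse_gaussian <- function(N, p, g, zero_mean = FALSE) {
  sd <- if (g > 0) g / sqrt(p * N) else 0
  mask <- matrix(runif(N * N) < p, N, N)
  vals <- matrix(0, N, N)
  nnz <- sum(mask)
  if (nnz > 0 && sd > 0) {
    vals[mask] <- rnorm(nnz, 0, sd)
    if (zero_mean && nnz > 0) {
      # shift the nonzero entries so the realized sum over ALL entries is 0
      vals[mask] <- vals[mask] - sum(vals) / nnz
    }
  }
  vals
}

#' Initialize network connectivity
#'
#' Draws the weight structures described by a [connectivity_spec()]:
#' `G` sparse Gaussian with sd `g_g / sqrt(p_g * N)` on a Bernoulli(`p_g`)
#' mask; `M` Gaussian with sd `g_m / sqrt(p_m * N)` (dense when `p_m = 1`);
#' `Q` uniform on `[-3 / sqrt(K), 3 / sqrt(K)]`; `W` all zeros; `W_in`
#' uniform on `[-1, 1]`.  The draw is deterministic given `spec$seed`.
#'
#' @param spec a [connectivity_spec()].
#' @param zero_mean if `TRUE`, shift the realized nonzero entries of `G`
#'   and `M` so each matrix sums to zero exactly (used for the spiking
#'   network to counterbalance firing-rate heterogeneity).
#' @return An object of class `pa_connectivity`: a list with elements
#'   `G` (a sparse [`Matrix::dgCMatrix-class`]), `M`, `W`, `Q`, `W_in`
#'   and the originating `spec`.
#' @export
init_connectivity <- function(spec, zero_mean = FALSE) {
  stopifnot(inherits(spec, "connectivity_spec"))
  set.seed(spec$seed)
  N <- spec$N
  G <- draw_sparse_gaussian(N, spec$p_g, spec$g_g, zero_mean)
  M <- draw_sparse_gaussian(N, spec$p_m, spec$g_m, zero_mean)
  Q <- matrix(runif(N * spec$K, -3 / sqrt(spec$K), 3 / sqrt(spec$K)),
              N, spec$K)
  W <- matrix(0, spec$K, N)
  W_in <- if (spec$n_in > 0) {
    matrix(runif(N * spec$n_in, -1, 1), N, spec$n_in)
  } else {
    matrix(0, N, 0)
  }
  structure(
    list(G = Matrix::Matrix(G, sparse = TRUE),
         M = M, W = W, Q = Q, W_in = W_in, spec = spec,
         feedback = "none"),
    class = "pa_connectivity")
}

#' @export
print.pa_connectivity <- function(x, ...) {
  cat("pa_connectivity\n")
  print(x$spec)
  cat(sprintf("  ||M||_F = %.4g, ||W||_F = %.4g, feedback = %s\n",
              norm(x$M, "F"), norm(x$W, "F"), x$feedback))
  invisible(x)
}

#' Write connectivity to a directory of plain-text arrays
#'
#' Each matrix is stored as a headerless CSV, with the spec as JSON.
#' A plain-text container is used so that runs remain portable and
#' diff-able; [read_connectivity()] restores the object.
#'
#' @param conn a `pa_connectivity`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(conn, dir) {
  stopifnot(inherits(conn, "pa_connectivity"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, name) {
    utils::write.table(as.matrix(m), file.path(dir, paste0(name, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  wm(conn$G, "G"); wm(conn$M, "M"); wm(conn$W, "W"); wm(conn$Q, "Q")
  if (ncol(conn$W_in) > 0) wm(conn$W_in, "W_in")
  meta <- c(unclass(conn$spec), list(feedback = conn$feedback))
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- connectivity_spec(meta$N, meta$p_g, meta$g_g, meta$p_m, meta$g_m,
                            meta$K, meta$n_in, meta$seed)
  rm_ <- function(name) {
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".csv")),
                                sep = ",", header = FALSE))
  }
  G <- rm_("G")
  dimnames(G) <- NULL
  win_path <- file.path(dir, "W_in.csv")
  W_in <- if (file.exists(win_path)) unname(rm_("W_in")) else matrix(0, spec$N, 0)
  structure(
    list(G = Matrix::Matrix(G, sparse = TRUE),
         M = unname(rm_("M")), W = unname(rm_("W")), Q = unname(rm_("Q")),
         W_in = W_in, spec = spec,
         feedback = if (is.null(meta$feedback)) "none" else meta$feedback),
    class = "pa_connectivity")
}
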