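#' Construct a two-agent dose grid
#'
#' A dose grid holds the J x K lattice of (raw or standardized) dose values for
#' the two agents, together with optional single-agent "skeleton" toxicity
#' estimates used by the copula-type models and by dose standardization.
#'
#' @param u Numeric vector of length J, strictly increasing: doses of agent 1.
#' @param v Numeric vector of length K, strictly increasing: doses of agent 2.
#' @param skeleton_p Optional length-J vector in (0,1), strictly increasing:
#'   prior estimates of single-agent toxicity for agent 1.
#' @param skeleton_q Optional length-K vector in (0,1), strictly increasing:
#'   prior estimates of single-agent toxicity for agent 2.
#' @return An object of class `dose_grid` with fields `J`, `K`, `u`, `v`,
#'   `skeleton_p`, `skeleton_q`.
#' @examples
#' g <- dose_grid(u = c(0.5, 1, 1.5), v = c(0.5, 1, 1.5))
#' g$J
#' @export
dose_grid <- function(u, v, skeleton_p = NULL, skeleton_q = NULL) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) >= 1, length(v) >= 1)
  if (any(diff(u) <= 0)) stop("agent-1 doses `u` must be strictly increasing")
  if (any(diff(v) <= 0)) stop("agent-2 doses `v` must be strictly increasing")
  check_skel <- function(s, len, name) {
    if (is.null(s)) return(NULL)
    if (length(s) != len)
      stop(sprintf("`%s` must have length %d", name, len))
    if (any(s <= 0) || any(s >= 1))
      stop(sprintf("`%s` must lie in the open interval (0,1)", name))
    if (any(diff(s) <= 0))
      stop(sprintf("`%s` must be strictly increasing", name))
    as.numeric(s)
  }
  g <- structure(
    list(J = length(u), K = length(v),
         u = as.numeric(u), v = as.numeric(v),
         skeleton_p = check_skel(skeleton_p, length(u), "skeleton_p"),
         skeleton_q = check_skel(skeleton_q, length(v), "skeleton_q")),
    class = "dose_grid")
  g
}

#' Standardized dose grid from single-agent skeletons
#'
#' Builds a grid whose dose values are the logits of the single-agent skeleton
#' toxicity estimates, `u_j = logit(a_j)` and `v_k = logit(b_k)`, the common
#' standardization for logistic-type combination models. Skeletons straddling
#' 0.5 yield mixed-sign standardized doses.
#'
#' @param skeleton_p,skeleton_q Strictly increasing vectors in (0,1).
#' @return A `dose_grid`.
#' @export
std_dose_grid <- function(skeleton_p, skeleton_q) {
  dose_grid(u = stats::qlogis(skeleton_p), v = stats::qlogis(skeleton_q),
            skeleton_p = skeleton_p, skeleton_q = skeleton_q)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d\n", x$J, x$K))
  cat("  u:", signif(x$u, 4), "\n")
  cat("  v:", signif(x$v, 4), "\n")
  if (!is.null(x$skeleton_p)) cat("  skeleton_p:", x$skeleton_p, "\n")
  if (!is.null(x$skeleton_q)) cat("  skeleton_q:", x$skeleton_q, "\n")
  invisible(x)
}

is_on_grid <- function(grid, j, k) {
  j >= 1 && j <= grid$J && k >= 1 && k <= grid$K
}

# linear index of (j, k) in the column-flattened J x K matrix
dose_index <- function(grid, j, k) (k - 1L) * grid$J + j
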