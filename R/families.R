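# Registry of the published two-agent dose-toxicity families.
#
# Every family exposes, through `family_info()`:
#   dim(grid)        parameter dimension p
#   theta_names(grid)
#   needs_skeleton   copula families combine single-agent skeleton estimates
#   dose_range       admissible dose values ("any", "unit" = [0,1] with the
#                    log-linear family requiring u,v < 1)
#   eval(Theta, grid, jj, kk)  vectorized surface: Theta is an n x p matrix,
#                    jj/kk equal-length level-index vectors; returns an
#                    n x length(jj) matrix of toxicity probabilities
#   constraints(theta, grid)   named logical vector, TRUE = satisfied; strict
#                    inequalities enforced with margin .EPS_CONSTRAINT

.EPS_CONSTRAINT <- 1e-10

#' Model family names
#'
#' The eight published dose-toxicity families available in the package.
#' @return Character vector of family names.
#' @export
model_families <- function() {
  c("logistic4", "generalized_crm", "scaled_logistic", "change_point",
    "clayton", "gumbel", "log_linear", "six_param")
}

family_info <- function(family) {
  family <- match.arg(family, model_families())
  .FAMILIES[[family]]
}

.gt <- function(x) x > .EPS_CONSTRAINT   # strict "> 0" with numerical margin
.lt <- function(x) x < -.EPS_CONSTRAINT  # strict "< 0"

# --- logistic4: logit F = th1 + th2 u + th3 v + th4 u v ----------------------

.logistic4_eval <- function(Theta, grid, jj, kk) {
  u <- grid$u[jj]; v <- grid$v[kk]
  g <- Theta[, 1] + tcrossprod(Theta[, 2], u) + tcrossprod(Theta[, 3], v) +
    tcrossprod(Theta[, 4], u * v)
  stats::plogis(g)
}

.logistic4_constraints <- function(theta, grid) {
  c("theta2 > 0" = .gt(theta[2]),
    "theta3 > 0" = .gt(theta[3]),
    "theta2 + theta4*v_k > 0 for all k" = all(.gt(theta[2] + theta[4] * grid$v)),
    "theta3 + theta4*u_j > 0 for all j" = all(.gt(theta[3] + theta[4] * grid$u)))
}

# analytic gradient, used as the oracle cross-check for finite differences
.logistic4_grad <- function(theta, grid, j, k) {
  u <- grid$u[j]; v <- grid$v[k]
  g <- theta[1] + theta[2] * u + theta[3] * v + theta[4] * u * v
  f <- stats::plogis(g)
  f * (1 - f) * c(1, u, v, u * v)
}

# --- generalized CRM: logit F = alpha_k + beta u_j ---------------------------

.gcrm_eval <- function(Theta, grid, jj, kk) {
  K <- grid$K
  u <- grid$u[jj]
  a <- Theta[, kk, drop = FALSE]            # n x L: alpha_{k} per dose
  stats::plogis(a + tcrossprod(Theta[, K + 1], u))
}

.gcrm_constraints <- function(theta, grid) {
  K <- grid$K
  alph <- theta[seq_len(K)]
  c("beta > 0" = .gt(theta[K + 1]),
    "alpha_k strictly increasing in k" =
      K == 1 || all(.gt(diff(alph))))
}

# --- scaled logistic: F = rho * logit^-1(th1 + th2 u + th3 v) ----------------

.scaled_logistic_eval <- function(Theta, grid, jj, kk) {
  u <- grid$u[jj]; v <- grid$v[kk]
  g <- Theta[, 2] + tcrossprod(Theta[, 3], u) + tcrossprod(Theta[, 4], v)
  Theta[, 1] * stats::plogis(g)
}

.scaled_logistic_constraints <- function(theta, grid) {
  c("0 < rho < 1" = .gt(theta[1]) && .gt(1 - theta[1]),
    "theta2 > 0" = .gt(theta[3]),
    "theta3 > 0" = .gt(theta[4]))
}

# --- change point: logit F = min(alpha + beta u + gamma v, w) ----------------

.change_point_eval <- function(Theta, grid, jj, kk) {
  u <- grid$u[jj]; v <- grid$v[kk]
  g <- Theta[, 1] + tcrossprod(Theta[, 2], u) + tcrossprod(Theta[, 3], v)
  stats::plogis(pmin(g, Theta[, 4]))
}

.change_point_constraints <- function(theta, grid) {
  c("beta > 0" = .gt(theta[2]),
    "gamma > 0" = .gt(theta[3]))
}

# --- Clayton copula-type: F = 1 - {(1-p^a)^-g + (1-q^b)^-g - 1}^(-1/g) -------

# log1p(-(p^a)) computed stably; the bracket is >= 1 so its log is >= 0.
.clayton_eval <- function(Theta, grid, jj, kk) {
  p <- grid$skeleton_p[jj]; q <- grid$skeleton_q[kk]
  al <- Theta[, 1]; be <- Theta[, 2]; ga <- Theta[, 3]
  la <- -ga * log1p(-exp(tcrossprod(al, log(p))))  # log A, A = (1-p^a)^-g
  lb <- -ga * log1p(-exp(tcrossprod(be, log(q))))  # log B
  hi <- pmax(la, lb); lo <- pmin(la, lb)
  # log(A + B - 1) = hi + log(1 + exp(lo-hi) - exp(-hi))
  lsum <- hi + log1p(exp(lo - hi) - exp(-hi))
  1 - exp(-lsum / ga)
}

.copula_constraints <- function(theta, grid) {
  c("alpha > 0" = .gt(theta[1]),
    "beta > 0" = .gt(theta[2]),
    "gamma > 0" = .gt(theta[3]))
}

# --- Gumbel (FGM) copula-type ------------------------------------------------
# F = 1 - (1-p^a)(1-q^b) {1 + p^a q^b (e^g - 1)/(e^g + 1)}
# The brace term equals 1 + ab - 2ab/(e^g+1) as printed.

.gumbel_eval <- function(Theta, grid, jj, kk) {
  p <- grid$skeleton_p[jj]; q <- grid$skeleton_q[kk]
  a <- exp(tcrossprod(Theta[, 1], log(p)))
  b <- exp(tcrossprod(Theta[, 2], log(q)))
  gam <- tanh(Theta[, 3] / 2)               # (e^g - 1)/(e^g + 1)
  1 - (1 - a) * (1 - b) * (1 + a * b * gam)
}

# --- log-linear: log(1-F) = a log(1-u) + b log(1-v) + g log(1-u)log(1-v) -----

.log_linear_eval <- function(Theta, grid, jj, kk) {
  lu <- log1p(-grid$u[jj]); lv <- log1p(-grid$v[kk])
  G <- tcrossprod(Theta[, 1], lu) + tcrossprod(Theta[, 2], lv) +
    tcrossprod(Theta[, 3], lu * lv)
  -expm1(G)
}

.log_linear_constraints <- function(theta, grid) {
  c("alpha > 0" = .gt(theta[1]),
    "beta > 0" = .gt(theta[2]),
    "gamma < 0" = .lt(theta[3]))
}

# --- six-parameter model: F = G/(1+G) ----------------------------------------
# G = a1 u^b1 + a2 v^b2 + a3 (u^b1 v^b2)^b3, doses standardized to [0,1]

.six_param_eval <- function(Theta, grid, jj, kk) {
  u <- grid$u[jj]; v <- grid$v[kk]
  # x^b via exp(b log x); x = 0 handled as the b > 0 limit 0
  pow <- function(b, x) {
    lx <- ifelse(x > 0, log(x), -Inf)
    out <- exp(tcrossprod(b, lx))
    out[, x == 0] <- 0
    out
  }
  ub <- pow(Theta[, 4], u)                  # u^b1, n x L
  vb <- pow(Theta[, 5], v)                  # v^b2
  inter <- exp(Theta[, 6] * log(ub * vb))   # (u^b1 v^b2)^b3, 0 handled below
  inter[ub * vb == 0] <- 0
  G <- Theta[, 1] * ub + Theta[, 2] * vb + Theta[, 3] * inter
  G / (1 + G)
}

.six_param_constraints <- function(theta, grid) {
  c("alpha1 > 0" = .gt(theta[1]),
    "alpha2 > 0" = .gt(theta[2]),
    # vacuous at a zero dose, where the interaction term vanishes identically
    "alpha3*(v_k^beta2)^beta3 > 0 for all k" =
      all(.gt(theta[3] * (grid$v[grid$v > 0]^theta[5])^theta[6])),
    "alpha3*(u_j^beta1)^beta3 > 0 for all j" =
      all(.gt(theta[3] * (grid$u[grid$u > 0]^theta[4])^theta[6])),
    "beta1 > 0" = .gt(theta[4]),
    "beta2 > 0" = .gt(theta[5]),
    "beta3 > 0" = .gt(theta[6]))
}

.six_param_grad_a1 <- function(theta, grid, j, k) {
  # d F / d alpha1 = u^b1 / (1+G)^2 (chain rule through f(x) = x/(1+x))
  u <- grid$u[j]; v <- grid$v[k]
  ub <- u^theta[4]; vb <- v^theta[5]
  G <- theta[1] * ub + theta[2] * vb + theta[3] * (ub * vb)^theta[6]
  ub / (1 + G)^2
}

.FAMILIES <- list(
  logistic4 = list(
    dim = function(grid) 4L,
    theta_names = function(grid) paste0("theta", 1:4),
    needs_skeleton = FALSE, dose_range = "any",
    eval = .logistic4_eval, constraints = .logistic4_constraints,
    grad = .logistic4_grad),
  generalized_crm = list(
    dim = function(grid) grid$K + 1L,
    theta_names = function(grid) c(paste0("alpha", seq_len(grid$K)), "beta"),
    needs_skeleton = FALSE, dose_range = "any",
    eval = .gcrm_eval, constraints = .gcrm_constraints,
    grad = NULL),
  scaled_logistic = list(
    dim = function(grid) 4L,
    theta_names = function(grid) c("rho", "theta1", "theta2", "theta3"),
    needs_skeleton = FALSE, dose_range = "any",
    eval = .scaled_logistic_eval, constraints = .scaled_logistic_constraints,
    grad = NULL),
  change_point = list(
    dim = function(grid) 4L,
    theta_names = function(grid) c("alpha", "beta", "gamma", "w"),
    needs_skeleton = FALSE, dose_range = "any",
    eval = .change_point_eval, constraints = .change_point_constraints,
    grad = NULL),
  clayton = list(
    dim = function(grid) 3L,
    theta_names = function(grid) c("alpha", "beta", "gamma"),
    needs_skeleton = TRUE, dose_range = "any",
    eval = .clayton_eval, constraints = .copula_constraints,
    grad = NULL),
  gumbel = list(
    dim = function(grid) 3L,
    theta_names = function(grid) c("alpha", "beta", "gamma"),
    needs_skeleton = TRUE, dose_range = "any",
    eval = .gumbel_eval, constraints = .copula_constraints,
    grad = NULL),
  log_linear = list(
    dim = function(grid) 3L,
    theta_names = function(grid) c("alpha", "beta", "gamma"),
    needs_skeleton = FALSE, dose_range = "unit_open",
    eval = .log_linear_eval, constraints = .log_linear_constraints,
    grad = NULL),
  six_param = list(
    dim = function(grid) 6L,
    theta_names = function(grid) c("alpha1", "alpha2", "alpha3",
                                   "beta1", "beta2", "beta3"),
    needs_skeleton = FALSE, dose_range = "unit",
    eval = .six_param_eval, constraints = .six_param_constraints,
    grad = NULL)
)

# family/grid compatibility guard shared by model_spec() and integrators
check_family_grid <- function(family, grid) {
  info <- family_info(family)
  if (info$needs_skeleton &&
      (is.null(grid$skeleton_p) || is.null(grid$skeleton_q)))
    stop(sprintf(
      "family '%s' combines single-agent skeletons: the grid must carry skeleton_p and skeleton_q",
      family), call. = FALSE)
  if (identical(info$dose_range, "unit_open") &&
      (any(grid$u >= 1) || any(grid$v >= 1)))
    stop(sprintf("family '%s' requires doses u_j, v_k < 1", family),
         call. = FALSE)
  if (identical(info$dose_range, "unit") &&
      (any(grid$u < 0) || any(grid$u > 1) || any(grid$v < 0) || any(grid$v > 1)))
    stop(sprintf("family '%s' requires standardized doses in [0, 1]", family),
         call. = FALSE)
  invisible(info)
}
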