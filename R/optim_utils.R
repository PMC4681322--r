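# Multi-start Levenberg-Marquardt driver used by the staged SANS fitter and
# the Carreau fitter. Parameters are expected in an unconstrained (typically
# log) space; starts beyond the first are log-uniform perturbations of th0.
# The perturbation stream has its own fixed seed so that fits are
# deterministic and leave the caller's RNG state untouched.
.multistart_lm <- function(resid_fn, th0, n_starts = 10, spread = 1,
                           ftol = 1e-10) {
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = 1e-10,
                                     maxiter = 300)
  starts <- list(th0)
  if (n_starts > 1) {
    pert <- withr::with_seed(424243L, {
      matrix(stats::runif((n_starts - 1) * length(th0), -spread, spread),
             ncol = length(th0))
    })
    for (i in seq_len(n_starts - 1)) starts[[i + 1]] <- th0 + pert[i, ]
  }
  best <- NULL
  best_cost <- Inf
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(par = s, fn = resid_fn, control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    cost <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    any_conv <- any_conv || conv
    if (cost < best_cost) {
      best_cost <- cost
      best <- fit
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  list(par = best$par, fvec = best$fvec, hessian = best$hessian,
       converged = any_conv, cost = best_cost)
}
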