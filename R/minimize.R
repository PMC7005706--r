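# Local geometry optimization of the mobile atoms (slab stays fixed).

#' Locally minimize a molecular system
#'
#' Conjugate-gradient minimization of the total potential energy over
#' the mobile (non-fixed) atoms, followed by a quasi-Newton polish until
#' the gradient max-norm drops below `tol`.  Returns the relaxed system
#' together with its energy and, when a surface is present, the
#' single-point binding energy at the minimum.
#'
#' @param system A `molsys`.
#' @param params `ff_params`.
#' @param tol Convergence threshold on the gradient max-norm
#'   (kcal/mol/A, default 1e-4).
#' @param max_iter Iteration budget (default 2000, split between the CG
#'   stage and the polish).
#' @return List with `system`, `e_total`, `e_be` (NA without a surface),
#'   `converged`, `grad_max`.
#' @export
local_minimize <- function(system, params = default_forcefield(),
                           tol = 1e-4, max_iter = 2000) {
  mobile <- which(!system$atoms$fixed)
  if (!length(mobile)) {
    e <- total_energy(system, params)$total
    return(list(system = system, e_total = e, e_be = NA_real_,
                converged = TRUE, grad_max = 0))
  }
  x0 <- as.vector(t(system$coords[mobile, , drop = FALSE]))
  sys <- system
  fn <- function(x) {
    sys$coords[mobile, ] <- matrix(x, ncol = 3, byrow = TRUE)
    .kernel_sum(sys, params)
  }
  gr <- function(x) {
    sys$coords[mobile, ] <- matrix(x, ncol = 3, byrow = TRUE)
    k <- .kernel_eval(sys, params)
    -as.vector(t(k$forces[mobile, , drop = FALSE]))
  }
  # a short quasi-Newton capture first: CG line searches overshoot badly
  # on the steep r^-12 wall of clashed starts
  o0 <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                     control = list(maxit = min(200, max_iter), factr = 1e4))
  o1 <- stats::optim(o0$par, fn, gr, method = "CG",
                     control = list(maxit = max_iter, reltol = 1e-12))
  if (!is.finite(o1$value) || o1$value > o0$value) o1 <- o0
  o2 <- stats::optim(o1$par, fn, gr, method = "L-BFGS-B",
                     control = list(maxit = max_iter,
                                    factr = 10, pgtol = tol / 10))
  par <- if (o2$value <= o1$value) o2$par else o1$par
  g <- gr(par)
  gmax <- max(abs(g))
  converged <- gmax < tol
  if (!converged)
    warning(sprintf("minimization stopped at grad max-norm %.3g (tol %.3g)",
                    gmax, tol), call. = FALSE)
  out <- system
  out$coords[mobile, ] <- matrix(par, ncol = 3, byrow = TRUE)
  e_total <- total_energy(out, params)$total
  e_be <- if (any(out$atoms$group == "surface"))
    binding_energy(out, params = params)$e_be else NA_real_
  list(system = out, e_total = e_total, e_be = e_be,
       converged = converged, grad_max = gmax)
}

#' @keywords internal
.kernel_sum <- function(system, params) {
  k <- .kernel_eval(system, params)
  k$e_bond + k$e_angle + k$e_dihedral + k$e_lj + k$e_coul
}
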