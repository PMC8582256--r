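# Norm-extended optimization driver.
#
# The Levenberg-Marquardt step is recast as the lowest eigenvector of the
# gradient-scaled augmented ("bordered") Hessian
#   L(alpha) = [ 0        alpha g^T ]
#              [ alpha g      G     ]
# solved by split-Davidson microiterations that grow the subspace with
# configuration-only or orbital-only preconditioned residuals.  The step
# is x = y_body / (alpha y_0) with the projector applied to the CI part;
# alpha >= 1 is raised until ||x|| fits the trust radius, which Fletcher's
# rule adapts across macroiterations.

#' Apply the gradient-scaled augmented Hessian L(alpha)
#'
#' Acts on a bordered trial vector without materializing L.
#'
#' @param cep A `cep_state`.
#' @param alpha Gradient scaling (> 0).
#' @param trial List with `border` (scalar), `v_conf` (matrix layout or
#'   flat, may be NULL) and `v_orb` (packed, may be NULL).
#' @return List of the same shape holding `L(alpha) %*% trial`.
#' @export
l_alpha_apply <- function(cep, alpha, trial) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  basis <- cep$basis
  v_c <- if (is.null(trial$v_conf)) matrix(0, basis$n_str_a, basis$n_str_b)
         else ci_matrix(trial$v_conf, basis)
  v_o <- if (is.null(trial$v_orb)) numeric(cep$spaces$n_rot) else trial$v_orb
  b <- if (is.null(trial$border)) 0 else trial$border
  g_c <- cep$g_ci
  g_o <- cep$g_orb
  h <- hessian_apply(cep, v_c, v_o)
  list(border = alpha * (sum(g_c * v_c) + sum(g_o * v_o)),
       v_conf = alpha * b * g_c + h$v_conf,
       v_orb = alpha * b * g_o + h$v_orb)
}

#' Extract the NEO step from a bordered eigenvector
#'
#' Rescales the body of the eigenvector by its border component and alpha
#' and applies the projector to the CI part.
#'
#' @param y Full bordered vector: `c(border, ci part, orbital part)`.
#' @param alpha Gradient scaling used in L(alpha).
#' @param cep A `cep_state` (provides dimensions and the CEP vector).
#' @return List with `delta_c` (matrix layout) and `kappa` (packed), or an
#'   error when the border component vanishes (alpha too small).
#' @export
extract_step <- function(y, alpha, cep) {
  nd <- cep$basis$dim
  y0 <- y[1L]
  if (abs(y0) < 1e-10 * sqrt(sum(y^2))) {
    stop("vanishing border component in the NEO eigenvector; ",
         "increase alpha", call. = FALSE)
  }
  body <- y[-1L] / (alpha * y0)
  dc <- ci_matrix(body[seq_len(nd)], cep$basis)
  dc <- dc - sum(cep$c0 * dc) * cep$c0
  kappa <- body[nd + seq_len(cep$spaces$n_rot)]
  list(delta_c = dc, kappa = kappa)
}

#' Solve the step-length equation for alpha
#'
#' Safeguarded bisection on the monotone map alpha -> ||step(alpha)||.
#' Returns `alpha_min` when the step at `alpha_min` is already inside the
#' trust radius, otherwise the alpha with `||step|| = r_t` to the stated
#' relative tolerance.
#'
#' @param step_norm_fn Function alpha -> step norm.
#' @param r_t Trust radius (> 0).
#' @param alpha_min Smallest admissible alpha (default 1).
#' @param rel_tol Relative tolerance on the matched norm.
#' @export
solve_alpha <- function(step_norm_fn, r_t, alpha_min = 1, rel_tol = 1e-3) {
  if (r_t <= 0) stop("trust radius must be > 0", call. = FALSE)
  n0 <- step_norm_fn(alpha_min)
  if (!is.finite(n0) || n0 <= r_t) return(alpha_min)
  lo <- alpha_min
  hi <- alpha_min
  for (k in 1:40) {
    hi <- hi * 10
    nh <- step_norm_fn(hi)
    if (is.finite(nh) && nh <= r_t) break
    lo <- hi
    if (k == 40) stop("alpha bracket failure on [", alpha_min, ", ", hi, "]",
                      call. = FALSE)
  }
  for (k in 1:200) {
    mid <- sqrt(lo * hi)
    nm <- step_norm_fn(mid)
    if (is.finite(nm) && abs(nm - r_t) <= rel_tol * r_t) return(mid)
    if (!is.finite(nm) || nm > r_t) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  hi
}

#' Trust-region policy constants
#'
#' Fletcher-style accept/reject and radius adaptation: an energy increase
#' rejects the step and halves the radius; otherwise the radius is scaled
#' by `expand` when the predicted/actual ratio exceeds `hi`, by `shrink`
#' when it falls below `lo`, and kept otherwise, always within
#' `[r_min, r_max]`.
#'
#' @param r_init Initial trust radius.
#' @param r_min,r_max Radius bounds.
#' @param lo,hi Ratio thresholds.
#' @param expand,shrink,reject Radius factors.
#' @export
trust_region_policy <- function(r_init = 0.5, r_min = 1e-4, r_max = 1,
                                lo = 0.25, hi = 0.75,
                                expand = 1.2, shrink = 0.7, reject = 0.5) {
  list(r_init = r_init, r_min = r_min, r_max = r_max, lo = lo, hi = hi,
       expand = expand, shrink = shrink, reject = reject)
}

#' Fletcher trust-radius update
#'
#' @param e_new Energy after the trial step.
#' @param e_old CEP energy.
#' @param e_pred Energy predicted by the quadratic model at the step.
#' @param r_t Current trust radius.
#' @param policy A [trust_region_policy()].
#' @return List with `accept`, `r_t` (updated) and `ratio`.
#' @export
fletcher_update <- function(e_new, e_old, e_pred, r_t,
                            policy = trust_region_policy()) {
  pred <- e_pred - e_old
  ratio <- if (pred != 0) (e_new - e_old) / pred else 1
  if (e_new > e_old) {
    return(list(accept = FALSE,
                r_t = max(policy$r_min, r_t * policy$reject),
                ratio = ratio))
  }
  r_new <- if (ratio > policy$hi) {
    min(policy$r_max, r_t * policy$expand)
  } else if (ratio < policy$lo) {
    max(policy$r_min, r_t * policy$shrink)
  } else r_t
  list(accept = TRUE, r_t = r_new, ratio = ratio)
}

# --- split-Davidson microiterations ------------------------------------

# Solve the lowest eigenpair of L(alpha) over the bordered subspace
# spanned by e0 and the stored pure trial vectors.  Returns the projected
# eigenproblem solution for a given alpha.
subspace_eig <- function(alpha, b_coup, g_sub) {
  m <- length(b_coup)
  lmat <- matrix(0, m + 1L, m + 1L)
  lmat[1L, -1L] <- alpha * b_coup
  lmat[-1L, 1L] <- alpha * b_coup
  lmat[-1L, -1L] <- g_sub
  e <- eigen((lmat + t(lmat)) / 2, symmetric = TRUE)
  i <- which.min(e$values)
  list(value = e$values[i], y = e$vectors[, i])
}

subspace_step_norm <- function(alpha, b_coup, g_sub) {
  s <- subspace_eig(alpha, b_coup, g_sub)
  y0 <- s$y[1L]
  if (abs(y0) < 1e-12) return(Inf)
  sqrt(sum((s$y[-1L] / (alpha * y0))^2))
}

#' Split-Davidson solution of the NEO eigenproblem
#'
#' Grows a Krylov-like subspace with configuration-only or orbital-only
#' preconditioned residual vectors (whichever part has the larger
#' residual) until the bordered eigenpair residual falls below
#' `tol_micro`.  When a trust radius is given, alpha is re-solved on the
#' current subspace at every microiteration so the emerging step obeys
#' `||x|| <= r_t`; with `alpha` fixed the routine is an ordinary (split)
#' Davidson eigensolver for L(alpha).
#'
#' @param cep A `cep_state`.
#' @param tol_micro Residual 2-norm tolerance.
#' @param r_t Trust radius (used when `alpha` is NULL).
#' @param alpha Fixed gradient scaling, or NULL to control by `r_t`.
#' @param max_micro Maximum number of subspace expansions.
#' @param max_subspace Collapse threshold for the stored trial vectors.
#' @return List with the eigenvalue `lambda`, `alpha`, the step
#'   (`kappa`, `delta_c`), its norm, the predicted quadratic-model energy
#'   change `de_pred`, the microiteration count and the residual history.
#' @export
neo_micro <- function(cep, tol_micro = 1e-10, r_t = NULL, alpha = NULL,
                      max_micro = 100L, max_subspace = 50L) {
  basis <- cep$basis
  spaces <- cep$spaces
  nd <- basis$dim
  nr <- spaces$n_rot
  g_c <- as.numeric(cep$g_ci)
  g_o <- cep$g_orb
  diag_c <- 2 * (as.numeric(
    hamiltonian_diagonal(cep$active_h, cep$active_eri, basis)) - cep$e_active)
  diag_c[abs(diag_c) < 0.1] <- 0.1
  diag_o <- orbital_hessian_diagonal(cep)

  vec_c <- matrix(0, nd, 0L)   # conf-block orthonormal trials
  vec_o <- matrix(0, max(nr, 0L), 0L)
  gv_c <- list()               # G products of each stored trial
  gv_o <- list()
  types <- character(0)

  project_c <- function(v) {
    v <- v - sum(as.numeric(cep$c0) * v) * as.numeric(cep$c0)
    v
  }
  add_trial <- function(v, type) {
    if (type == "conf") {
      v <- project_c(v)
      v <- orthonormalize_against(v, vec_c)
      if (is.null(v)) return(FALSE)
      h <- hessian_apply(cep, v_conf = v, v_orb = NULL)
      vec_c <<- cbind(vec_c, v)
      gv_c[[length(types) + 1L]] <<- as.numeric(h$v_conf)
      gv_o[[length(types) + 1L]] <<- h$v_orb
      types <<- c(types, "conf")
    } else {
      v <- orthonormalize_against(v, vec_o)
      if (is.null(v)) return(FALSE)
      h <- hessian_apply(cep, v_conf = NULL, v_orb = v)
      vec_o <<- cbind(vec_o, v)
      gv_c[[length(types) + 1L]] <<- as.numeric(h$v_conf)
      gv_o[[length(types) + 1L]] <<- h$v_orb
      types <<- c(types, "orb")
    }
    TRUE
  }
  trial_column <- function(i) {
    # full-body representation of stored trial i
    v <- numeric(nd + nr)
    ic <- sum(types[seq_len(i)] == "conf")
    io <- i - ic
    if (types[i] == "conf") v[seq_len(nd)] <- vec_c[, ic]
    else v[nd + seq_len(nr)] <- vec_o[, io]
    v
  }

  # seed with preconditioned gradients
  seeded <- FALSE
  if (sqrt(sum(g_c^2)) > 1e-13) seeded <- add_trial(-g_c / diag_c, "conf") || seeded
  if (nr > 0L && sqrt(sum(g_o^2)) > 1e-13) {
    seeded <- add_trial(-g_o / diag_o, "orb") || seeded
  }
  if (!seeded) {
    return(list(lambda = 0, alpha = if (is.null(alpha)) 1 else alpha,
                kappa = numeric(nr),
                delta_c = matrix(0, basis$n_str_a, basis$n_str_b),
                step_norm = 0, de_pred = 0, n_micro = 0L,
                residuals = numeric(0), y = NULL))
  }

  resid_hist <- numeric(0)
  stagnant <- FALSE
  for (it in seq_len(max_micro)) {
    m <- length(types)
    b_coup <- vapply(seq_len(m), function(i) {
      ic <- sum(types[seq_len(i)] == "conf")
      if (types[i] == "conf") sum(g_c * vec_c[, ic])
      else sum(g_o * vec_o[, i - ic])
    }, numeric(1))
    g_sub <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        ic <- sum(types[seq_len(i)] == "conf")
        if (types[i] == "conf") {
          g_sub[i, j] <- sum(vec_c[, ic] * gv_c[[j]])
        } else {
          g_sub[i, j] <- sum(vec_o[, i - ic] * gv_o[[j]])
        }
      }
    }
    g_sub <- (g_sub + t(g_sub)) / 2
    a_cur <- if (is.null(alpha)) {
      solve_alpha(function(a) subspace_step_norm(a, b_coup, g_sub), r_t)
    } else alpha
    sol <- subspace_eig(a_cur, b_coup, g_sub)
    lambda <- sol$value
    y <- sol$y
    coeff <- y[-1L]
    # full-space residual of the bordered eigenpair
    r_border <- a_cur * sum(b_coup * coeff) - lambda * y[1L]
    r_c <- a_cur * y[1L] * g_c - lambda *
      (if (any(types == "conf")) vec_c %*% coeff[types == "conf"] else 0)
    r_o <- a_cur * y[1L] * g_o - lambda *
      (if (any(types == "orb")) vec_o %*% coeff[types == "orb"] else 0)
    r_c <- as.numeric(r_c)
    r_o <- as.numeric(r_o)
    for (j in seq_len(m)) {
      r_c <- r_c + coeff[j] * gv_c[[j]]
      r_o <- r_o + coeff[j] * gv_o[[j]]
    }
    rn <- sqrt(r_border^2 + sum(r_c^2) + sum(r_o^2))
    resid_hist <- c(resid_hist, rn)
    done <- rn <= tol_micro
    if (done || stagnant || it == max_micro) {
      y0 <- y[1L]
      if (abs(y0) < 1e-12) {
        stop("vanishing border component in the NEO eigenvector; ",
             "increase alpha", call. = FALSE)
      }
      s <- coeff / (a_cur * y0)
      kappa <- numeric(nr)
      dc <- numeric(nd)
      ic <- 0L; io <- 0L
      for (i in seq_len(m)) {
        if (types[i] == "conf") {
          ic <- ic + 1L
          dc <- dc + s[i] * vec_c[, ic]
        } else {
          io <- io + 1L
          kappa <- kappa + s[i] * vec_o[, io]
        }
      }
      dc <- project_c(dc)
      de_pred <- sum(b_coup * s) + 0.5 * sum(s * (g_sub %*% s))
      if (!done && !stagnant) {
        warning("NEO microiterations reached max_micro with residual ",
                format(rn), call. = FALSE)
      }
      return(list(lambda = lambda, alpha = a_cur, kappa = kappa,
                  delta_c = ci_matrix(dc, basis),
                  step_norm = sqrt(sum(s^2)), de_pred = de_pred,
                  n_micro = it, residuals = resid_hist, y = c(y[1L], s)))
    }
    # split expansion: precondition the part with the larger residual
    nc <- sqrt(sum(r_c^2))
    no <- sqrt(sum(r_o^2))
    pick_conf <- nc >= no
    added <- FALSE
    if (pick_conf && nc > 0) {
      added <- add_trial(-r_c / pmax(abs(diag_c - lambda), 1e-2), "conf")
    }
    if (!added && nr > 0L && no > 0) {
      added <- add_trial(-r_o / pmax(abs(diag_o - lambda), 1e-2), "orb")
    }
    if (!added && !pick_conf && nc > 0) {
      added <- add_trial(-r_c / pmax(abs(diag_c - lambda), 1e-2), "conf")
    }
    if (!added) {
      stagnant <- TRUE  # extract the current best step on the next pass
      next
    }
    if (length(types) > max_subspace) {
      warning("NEO subspace exceeded ", max_subspace,
              " vectors without convergence", call. = FALSE)
    }
  }
  stop("NEO microiterations failed to converge; residual history: ",
       paste(format(utils::tail(resid_hist, 5L), digits = 3),
             collapse = ", "), call. = FALSE)
}
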