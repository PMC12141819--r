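#' Solve for direct contributions of circulating nutrients
#'
#' Core linear system of the cross-tracer analysis. Under infusion of
#' tracer j, the normalized labeling of a tissue target metabolite is the
#' sum of each circulating nutrient's direct contribution weighted by that
#' nutrient's serum labeling under arm j:
#' `measured[j] = sum_i cross[j, i] * f[i]`, with `cross[j, j] = 1`
#' (a nutrient normalized to itself). Solving the system across arms
#' separates direct use of each nutrient from carbon that arrives via
#' interconversion through another measured nutrient.
#'
#' @param cross Square numeric matrix, one row per infusion arm and one
#'   column per nutrient: `cross[j, i]` is the normalized labeling of serum
#'   nutrient i when nutrient j is infused. Diagonal must be 1.
#' @param measured Numeric vector, `measured[j]` = normalized labeling of
#'   the tissue target under arm j.
#' @param nutrients Optional nutrient names (defaults to
#'   `colnames(cross)` or `nutrient1..k`).
#' @param constrain If `TRUE` (default) solve a least-squares problem
#'   subject to `0 <= f <= 1` and flag entries pinned at a bound; if
#'   `FALSE`, exact linear solve. The unconstrained solution is always
#'   retained alongside so boundary-active estimates are visible.
#' @param max_condition Condition-number cutoff above which the system is
#'   declared singular (default 1e8).
#' @return An object of class `direct_contrib`; see [tidy.direct_contrib()]
#'   and [glance.direct_contrib()].
#' @examples
#' direct_contributions(rbind(c(1, 0.2), c(0.3, 1)), c(0.5, 0.4))
#' @export
direct_contributions <- function(cross, measured, nutrients = NULL,
                                 constrain = TRUE, max_condition = 1e8) {
  cross <- as.matrix(cross)
  k <- nrow(cross)
  if (is.null(k) || k != ncol(cross)) {
    stop_shape("Cross-labeling matrix must be square.")
  }
  if (length(measured) != k) {
    stop_shape("measured vector length must match the cross matrix dimension.")
  }
  if (any(abs(diag(cross) - 1) > 1e-8)) {
    stop_shape("Cross-labeling matrix diagonal must be 1 (self-normalization).")
  }
  if (any(cross < 0) || any(cross > 1.5) ||
      any(measured < 0) || any(measured > 1.5)) {
    stop_domain("Normalized labelings outside the QC bound [0, 1.5].")
  }
  if (is.null(nutrients)) {
    nutrients <- colnames(cross) %||% paste0("nutrient", seq_len(k))
  }
  cond <- kappa(cross, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    stop_singular_system(paste0(
      "Cross-labeling system is singular or ill-conditioned (condition number ",
      format(cond, digits = 3), ")."))
  }

  unconstrained <- as.numeric(solve(cross, measured))
  if (constrain) {
    if (all(unconstrained >= 0 & unconstrained <= 1)) {
      # interior exact solution is the constrained optimum (residual zero)
      f <- unconstrained
    } else {
      f <- bounded_lsq(cross, measured, start = pmin(pmax(unconstrained, 0), 1))
    }
    clipped <- (f < 1e-8 & unconstrained < 0) | (f > 1 - 1e-8 & unconstrained > 1)
  } else {
    f <- unconstrained
    clipped <- rep(FALSE, k)
  }
  residual <- sqrt(sum((cross %*% f - measured)^2))

  structure(
    list(
      nutrients = nutrients,
      contributions = setNames(as.numeric(f), nutrients),
      unconstrained = setNames(unconstrained, nutrients),
      clipped = setNames(clipped, nutrients),
      residual = residual,
      condition = cond,
      constrained = constrain,
      cross = cross,
      measured = as.numeric(measured)
    ),
    class = "direct_contrib"
  )
}

# box-constrained least squares on [0,1]^k via projected quasi-Newton;
# dimensions here are tiny (2-3 nutrients) so L-BFGS-B with an analytic
# gradient converges to well below grid resolution
bounded_lsq <- function(a, b, start) {
  fn <- function(f) sum((a %*% f - b)^2)
  gr <- function(f) as.numeric(2 * crossprod(a, a %*% f - b))
  fit <- optim(start, fn, gr, method = "L-BFGS-B",
               lower = rep(0, length(start)), upper = rep(1, length(start)),
               control = list(factr = 10, pgtol = 1e-14, maxit = 500))
  fit$par
}

#' @export
print.direct_contrib <- function(x, ...) {
  cat("Direct nutrient contributions (", if (x$constrained) "constrained to [0,1]"
      else "unconstrained", ")\n", sep = "")
  for (i in seq_along(x$nutrients)) {
    cat(sprintf("  %-12s %.4f%s\n", x$nutrients[i], x$contributions[i],
                if (x$clipped[i]) "  [at bound]" else ""))
  }
  cat(sprintf("  residual %.3g, condition number %.3g\n", x$residual, x$condition))
  invisible(x)
}

#' Tidy a direct-contribution fit
#'
#' One row per nutrient with the constrained estimate, the unconstrained
#' exact solution and whether the constrained fit is pinned at a bound.
#'
#' @param x A `direct_contrib` object.
#' @param ... Unused.
#' @return A tibble with columns `nutrient`, `contribution`,
#'   `unconstrained`, `clipped`.
#' @export
tidy.direct_contrib <- function(x, ...) {
  tibble(
    nutrient = x$nutrients,
    contribution = as.numeric(x$contributions),
    unconstrained = as.numeric(x$unconstrained),
    clipped = as.logical(x$clipped)
  )
}

#' One-row summary of a direct-contribution fit
#'
#' @param x A `direct_contrib` object.
#' @param ... Unused.
#' @return A tibble with `residual`, `condition_number`, `n_clipped`,
#'   `total_contribution`.
#' @export
glance.direct_contrib <- function(x, ...) {
  tibble(
    residual = x$residual,
    condition_number = x$condition,
    n_clipped = sum(x$clipped),
    total_contribution = sum(x$contributions)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
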