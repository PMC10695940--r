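# Material and spring models.  Units throughout: mm, N, MPa (N/mm^2), days.

#' Calvarial bone material model
#'
#' Isotropic elastic shell material with an optional Prony-series relaxation
#' describing the viscoelastic reshaping of the paediatric calvarium over
#' time.  The quasi-elastic effective modulus at time `t` is
#' `E(t) = E * (g_inf + sum_i g_i exp(-t / tau_i))` with
#' `g_inf = 1 - sum_i g_i`.
#'
#' The defaults are E = 1300 MPa and nu = 0.22 (literature values for
#' paediatric calvarial bone around two years of age).  The relaxation
#' weights are exposed explicitly because reported long-term ICV gains of
#' 10-20% require substantial stress relaxation; the default single term
#' (g = 0.9, tau = 7 days) leaves a long-term modulus of 10% of the
#' instantaneous one.
#'
#' @param E instantaneous Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @param prony list of terms `list(g =, tau =)`; `tau` in days. Empty list
#'   gives a purely elastic material.
#' @return object of class `material_model`.
#' @export
material_model <- function(E = 1300, nu = 0.22,
                           prony = list(list(g = 0.9, tau = 7))) {
  stopifnot(is.finite(E), E > 0, is.finite(nu), nu >= 0, nu < 0.5)
  g <- vapply(prony, function(p) p$g, numeric(1))
  tau <- vapply(prony, function(p) p$tau, numeric(1))
  if (any(g <= 0) || any(tau <= 0)) {
    stop("Prony weights and time constants must be positive", call. = FALSE)
  }
  g_inf <- 1 - sum(g)
  if (g_inf <= 0 || g_inf > 1) {
    stop("Prony weights must sum to less than 1 (g_inf in (0, 1])", call. = FALSE)
  }
  structure(list(E = E, nu = nu, g = g, tau = tau, g_inf = g_inf),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("<material_model> E = %.0f MPa, nu = %.2f, g_inf = %.2f",
              x$E, x$nu, x$g_inf))
  if (length(x$g)) {
    cat(", prony:", paste(sprintf("(g=%.2f, tau=%.1f d)", x$g, x$tau),
                          collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# E(t)/E0 relaxation factor
relax_factor <- function(material, t) {
  material$g_inf + if (length(material$g)) {
    sum(material$g * exp(-t / material$tau))
  } else 0
}

# registry of the prefabricated torsional spring distractors: natural opening
# 60 mm between the tips for all models; stiffness grows with wire diameter
SPRING_REGISTRY <- list(
  S10 = list(name = "S10", wire_diameter = 1.0, k = 0.17, L0 = 60),
  S12 = list(name = "S12", wire_diameter = 1.2, k = 0.39, L0 = 60),
  S14 = list(name = "S14", wire_diameter = 1.4, k = 0.68, L0 = 60)
)

#' Spring distractor model
#'
#' @param name `"S10"`, `"S12"` or `"S14"` (wire diameters 1.0/1.2/1.4 mm,
#'   stiffness 0.17/0.39/0.68 N/mm, natural opening 60 mm between the tips).
#' @return object of class `spring_model` with fields `name`,
#'   `wire_diameter` (mm), `k` (N/mm), `L0` (mm).
#' @export
spring_model <- function(name = c("S10", "S12", "S14")) {
  name <- match.arg(name)
  structure(SPRING_REGISTRY[[name]], class = "spring_model")
}

#' Spring force at a given opening
#'
#' The pre-compressed torsional spring pushes its two notch tips apart with a
#' force linear in the remaining compression, `k * (L0 - opening)`, and
#' disengages once the natural opening of 60 mm is reached.
#'
#' @param spring a [spring_model()] (or a model name).
#' @param opening current tip-to-tip distance, mm (non-negative).
#' @return force in N along the line joining the notches, pushing them apart.
#' @examples
#' spring_force(spring_model("S10"), 40)  # 0.17 * 20 = 3.4 N
#' @export
spring_force <- function(spring, opening) {
  if (is.character(spring)) spring <- spring_model(spring)
  stopifnot(inherits(spring, "spring_model"))
  if (any(!is.finite(opening)) || any(opening < 0)) {
    stop("spring opening must be non-negative", call. = FALSE)
  }
  ifelse(opening < spring$L0, spring$k * (spring$L0 - opening), 0)
}
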