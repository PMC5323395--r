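# Schild's Ladder parallel transport of a subject's longitudinal change into
# template space. A single geometric ladder is built per subject: the
# within-subject anatomical correspondence (baseline I0 to follow-up I1) is
# carried along the inter-subject path from the template T0, producing a
# template-space follow-up T1 whose registration to T0 yields the normalized
# SVF. This variant works on images directly and needs no BCH approximation.

#' Schild's Ladder transport of longitudinal change into template space
#'
#' Executes the single-ladder construction:
#' 1. register the template to the subject follow-up:
#'    `v1 = logdemons_register(I1, T0)$svf`;
#' 2. form the half-space image `P = T0 o Exp(0.5 v1)`;
#' 3. register the subject baseline to the half-space image:
#'    `v2 = logdemons_register(P, I0)$svf`;
#' 4. double the rung: `T1 = I0 o Exp(2 v2)` (for a stationary field the
#'    squared deformation is exactly `Exp(2 v)`; deformation-level
#'    self-composition is available via `doubling = "compose"`);
#' 5. register `v_norm = logdemons_register(T1, T0)$svf`.
#'
#' The returned `v_norm` is the subject's longitudinal SVF expressed in
#' template space; the intermediates `P` and `T1` are kept for audit.
#'
#' @param T0 template image ([scalar_volume()]).
#' @param I0,I1 subject baseline and follow-up images, globally pre-aligned
#'   with the template.
#' @param cfg a [registration_config()].
#' @param doubling how to realize the doubled rung deformation: `"svf"`
#'   (default, `Exp(2 v)`) or `"compose"` (self-composition of `Exp(v)`).
#' @return An object of class `schilds_ladder`: list with `v_norm`
#'   ([velocity_field()]), intermediates `P` and `T1`, and the inner SVFs
#'   `v_template_to_followup` and `v_baseline_to_half`.
#' @export
schilds_ladder <- function(T0, I0, I1, cfg = registration_config(),
                           doubling = c("svf", "compose")) {
  doubling <- match.arg(doubling)
  T0 <- as_volume(T0); I0 <- as_volume(I0); I1 <- as_volume(I1)
  check_same_grid(T0, I0, "template and baseline")
  check_same_grid(T0, I1, "template and follow-up")

  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("schilds_ladder [%s]: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  v1 <- step("template->followup", logdemons_register(I1, T0, cfg)$svf)
  P <- step("half-space image", warp_image(T0, exp_svf(v1, 0.5)))
  v2 <- step("baseline->half", logdemons_register(P, I0, cfg)$svf)
  phi2 <- if (doubling == "svf") {
    exp_svf(v2, 2)
  } else {
    ph <- exp_svf(v2, 1)
    compose(ph, ph)
  }
  T1 <- step("doubled rung", warp_image(I0, phi2))
  v_norm <- step("template->transported followup",
                 logdemons_register(T1, T0, cfg)$svf)
  structure(list(v_norm = v_norm, T1 = T1, P = P,
                 v_template_to_followup = v1, v_baseline_to_half = v2),
            class = "schilds_ladder")
}

#' @export
print.schilds_ladder <- function(x, ...) {
  cat(sprintf("<schilds_ladder: max |v_norm| = %.3g voxels>\n",
              max_vector_norm(x$v_norm)))
  invisible(x)
}
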