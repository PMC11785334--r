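#' Simulated participant profile
#'
#' Bundles a participant's group assignment and the latent parameters that
#' drive their simulated behaviour: baseline peak speed (vigour), its
#' per-trial learning slope, baseline via-point trough fraction (fusion) and
#' its slope, kinematic noise, and latent working-memory ability.
#'
#' @param id Participant identifier.
#' @param reward_group `"Rew"` or `"NoRew"`.
#' @param drug_group `"Halo"` or `"Ctrl"`.
#' @param vigour0 Baseline segment peak speed, cm/s (> 0).
#' @param vigour_slope Per-trial change in peak speed, cm/s per trial.
#' @param fusion0 Baseline trough-to-mean-peak speed fraction, in [0, 1).
#' @param fusion_slope Per-trial change in the trough fraction, 1/trial.
#' @param noise_sd Additive Gaussian positional noise, cm (>= 0).
#' @param wm_true Latent working-memory ability (unitless, ~N(0,1) scale).
#' @return A list of class `participant_profile`.
#' @export
participant_profile <- function(id, reward_group = c("Rew", "NoRew"),
                                drug_group = c("Halo", "Ctrl"),
                                vigour0 = 35, vigour_slope = 0,
                                fusion0 = 0.1, fusion_slope = 0,
                                noise_sd = 0.03, wm_true = 0) {
  reward_group <- match.arg(reward_group)
  drug_group <- match.arg(drug_group)
  stopifnot(vigour0 > 0, fusion0 >= 0, fusion0 < 1, noise_sd >= 0)
  structure(
    list(id = id, reward_group = reward_group, drug_group = drug_group,
         vigour0 = vigour0, vigour_slope = vigour_slope,
         fusion0 = fusion0, fusion_slope = fusion_slope,
         noise_sd = noise_sd, wm_true = wm_true),
    class = "participant_profile"
  )
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "participant %s [%s/%s]: vigour %.1f %+.4f cm/s/trial, fusion %.2f %+.5f /trial, noise sd %.3f cm\n",
    x$id, x$reward_group, x$drug_group, x$vigour0, x$vigour_slope,
    x$fusion0, x$fusion_slope, x$noise_sd))
  invisible(x)
}
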