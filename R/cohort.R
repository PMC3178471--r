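#' Synthetic cohort of bifurcation radius triples
#'
#' Draws a cohort with the statistical structure reported for carotid
#' bifurcations: ICA/CCA and ECA/CCA radius ratios from truncated normal
#' distributions on (0, 1) and an absolute CCA radius from a lognormal
#' distribution. Each subject contributes a left and a right
#' bifurcation, drawn independently. Optionally the daughter radii of
#' every row are rescaled by a common factor so the bifurcation power
#' law \eqn{r_{CCA}^n = r_{ICA}^n + r_{ECA}^n} holds exactly at a chosen
#' exponent (this preserves the ECA/ICA ratio), and multiplicative
#' Gaussian jitter can be added afterwards.
#'
#' Default ratio distributions are ICA/CCA ~ N(0.67, 0.074) and
#' ECA/CCA ~ N(0.61, 0.087) truncated to (0, 1), matching reported
#' carotid cohorts (inscribed-sphere measurements); the CCA radius is
#' lognormal with median 4 mm. The two ratio draws are uncorrelated by
#' default; `ratio_correlation` exposes the latent normal correlation.
#'
#' @param n_subjects number of subjects (> 0); the table has
#'   `2 * n_subjects` rows (left and right).
#' @param ica_ratio_mean,ica_ratio_sd ICA/CCA ratio distribution.
#' @param eca_ratio_mean,eca_ratio_sd ECA/CCA ratio distribution.
#' @param cca_meanlog,cca_sdlog lognormal parameters of the CCA radius
#'   (mm); defaults give median 4 mm.
#' @param ratio_correlation correlation of the latent normals behind the
#'   two ratio draws, in (-1, 1).
#' @param exact_exponent optional n; when set, daughters are rescaled so
#'   the power law holds exactly at n (to machine precision) before noise.
#' @param noise_sd relative (multiplicative) radius jitter SD.
#' @param seed optional integer seed; identical seeds give identical
#'   tables.
#' @return data.frame with columns `subject_id`, `side`, `r_cca_mm`,
#'   `r_ica_mm`, `r_eca_mm`.
#' @examples
#' coh <- sample_cohort(45, exact_exponent = 1.58, seed = 1)
#' range(coh$r_cca_mm)
#' @export
sample_cohort <- function(n_subjects,
                          ica_ratio_mean = 0.67, ica_ratio_sd = 0.074,
                          eca_ratio_mean = 0.61, eca_ratio_sd = 0.087,
                          cca_meanlog = log(4), cca_sdlog = 0.12,
                          ratio_correlation = 0,
                          exact_exponent = NULL,
                          noise_sd = 0,
                          seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects <= 0)
    stopf("n_subjects must be a positive count")
  n_subjects <- as.integer(n_subjects)
  if (abs(ratio_correlation) >= 1)
    stopf("ratio_correlation must be in (-1, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- 2L * n_subjects
  # correlated truncated-normal ratio pairs by joint rejection
  ica <- eca <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    z1 <- rnorm(length(todo))
    z2 <- ratio_correlation * z1 +
      sqrt(1 - ratio_correlation^2) * rnorm(length(todo))
    a <- ica_ratio_mean + ica_ratio_sd * z1
    b <- eca_ratio_mean + eca_ratio_sd * z2
    ok <- a > 0 & a < 1 & b > 0 & b < 1
    ica[todo[ok]] <- a[ok]
    eca[todo[ok]] <- b[ok]
    todo <- todo[!ok]
  }
  r_cca <- rlnorm(n, cca_meanlog, cca_sdlog)
  r_ica <- ica * r_cca
  r_eca <- eca * r_cca

  if (!is.null(exact_exponent)) {
    nn <- exact_exponent
    if (nn <= 0) stopf("exact_exponent must be > 0")
    scale <- (r_cca^nn / (r_ica^nn + r_eca^nn))^(1 / nn)
    r_ica <- r_ica * scale
    r_eca <- r_eca * scale
  }
  if (noise_sd > 0) {
    r_cca <- r_cca * (1 + rnorm(n, 0, noise_sd))
    r_ica <- r_ica * (1 + rnorm(n, 0, noise_sd))
    r_eca <- r_eca * (1 + rnorm(n, 0, noise_sd))
    if (any(c(r_cca, r_ica, r_eca) <= 0))
      stopf("noise_sd too large: produced non-positive radii")
  }

  data.frame(subject_id = rep(sprintf("S%03d", seq_len(n_subjects)),
                              each = 2L),
             side = rep(c("left", "right"), n_subjects),
             r_cca_mm = r_cca, r_ica_mm = r_ica, r_eca_mm = r_eca,
             stringsAsFactors = FALSE)
}
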