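#' Solve the bifurcation power law for one radius triple
#'
#' Finds the exponent n satisfying
#' \deqn{(r_{ICA}/r_{CCA})^n + (r_{ECA}/r_{CCA})^n = 1}
#' by Brent/zeroin bracketing root finding ([stats::uniroot()]). When
#' both daughter ratios are below 1 the left side is strictly
#' decreasing in n from 2 toward 0, so the root exists and is unique.
#' When either daughter radius is at least the parent radius the left
#' side never reaches 1 from above and no positive root exists: the
#' solver returns `NA` with status `"no_root"`. A root that falls
#' outside the bracket returns status `"out_of_bracket"`.
#'
#' @param triple a [radius_triple()] or numeric length 3
#'   `(r_cca, r_ica, r_eca)`, all > 0.
#' @param bracket search interval for n.
#' @param tol root-finding tolerance.
#' @return list with elements `n` (numeric or NA) and `status`
#'   (`"ok"`, `"no_root"` or `"out_of_bracket"`).
#' @examples
#' solve_exponent(c(5, 4, 3))$n   # 2: daughter areas sum to parent area
#' solve_exponent(c(1, 2^(-1/3), 2^(-1/3)))$n  # 3: symmetric cube law
#' @export
solve_exponent <- function(triple, bracket = c(0.05, 50), tol = 1e-10) {
  r <- as_triple_vector(triple)
  a <- r[2] / r[1]
  b <- r[3] / r[1]
  if (a >= 1 || b >= 1)
    return(list(n = NA_real_, status = "no_root"))
  g <- function(n) a^n + b^n - 1
  if (g(bracket[1]) < 0 || g(bracket[2]) > 0)
    return(list(n = NA_real_, status = "out_of_bracket"))
  root <- uniroot(g, interval = bracket, tol = tol)$root
  list(n = root, status = "ok")
}

as_triple_vector <- function(triple) {
  if (inherits(triple, "radius_triple"))
    r <- c(triple$r_cca, triple$r_ica, triple$r_eca)
  else r <- as.numeric(triple)[1:3]
  if (any(!is.finite(r)) || any(r <= 0))
    stopf("all radii must be positive and finite")
  r
}

# standardize a records table: accepts r_*_mm or r_* column names
get_triples <- function(records) {
  nm <- names(records)
  pick <- function(base) {
    cand <- c(paste0(base, "_mm"), base)
    hit <- cand[cand %in% nm]
    if (!length(hit))
      stopf("records must contain a column %s or %s", cand[1], cand[2])
    records[[hit[1]]]
  }
  data.frame(r_cca = pick("r_cca"), r_ica = pick("r_ica"),
             r_eca = pick("r_eca"))
}

#' Per-bifurcation exponents for a records table
#'
#' Runs [solve_exponent()] on every row and appends `n` and
#' `solve_status` columns.
#'
#' @param records data.frame with radius columns `r_cca_mm`, `r_ica_mm`,
#'   `r_eca_mm` (or without the `_mm` suffix).
#' @param bracket,tol passed to [solve_exponent()].
#' @return `records` with columns `n` and `solve_status` added.
#' @export
add_exponents <- function(records, bracket = c(0.05, 50), tol = 1e-10) {
  tr <- get_triples(records)
  sol <- lapply(seq_len(nrow(tr)), function(i)
    solve_exponent(as.numeric(tr[i, ]), bracket = bracket, tol = tol))
  records$n <- vapply(sol, function(s) s$n, numeric(1))
  records$solve_status <- vapply(sol, function(s) s$status, character(1))
  records
}

#' Mean of per-bifurcation exponents
#'
#' Arithmetic mean of the root-finding exponents over records whose
#' solver status is `"ok"`; rows without a root are excluded and
#' counted. Note this estimator and the cohort regression
#' ([fit_cohort_exponent()]) answer slightly different questions and
#' differ on noisy cohorts (the regression weights large-radius
#' bifurcations more); both converge to the generating exponent on
#' noiseless cohorts.
#'
#' @param records data.frame of radius triples; `n`/`solve_status`
#'   columns are computed with [add_exponents()] if missing.
#' @return the mean exponent, with attributes `n_used` and `n_excluded`.
#' @export
mean_individual_exponent <- function(records) {
  if (!all(c("n", "solve_status") %in% names(records)))
    records <- add_exponents(records)
  ok <- records$solve_status == "ok"
  if (!any(ok))
    stopf("no records with a solvable exponent (all no_root/out_of_bracket)")
  structure(mean(records$n[ok]),
            n_used = sum(ok), n_excluded = sum(!ok))
}

#' ICA radius change needed to satisfy the power law
#'
#' Percent change in the ICA radius that would make the triple satisfy
#' the power law at exponent n exactly, holding the CCA and ECA radii
#' fixed: the adjusted radius is
#' \eqn{r'_{ICA} = (r_{CCA}^n - r_{ECA}^n)^{1/n}}.
#'
#' @param triple a [radius_triple()] or numeric length 3; requires
#'   `r_eca < r_cca` for a real solution.
#' @param n exponent (> 0).
#' @return percent change `100 * (r'_ica - r_ica) / r_ica`.
#' @examples
#' ica_adjustment(c(1, 0.67, 0.61), n = 2)  # ~ +18.3
#' ica_adjustment(c(1, 0.67, 0.61), n = 3)  # ~ +37.0
#' @export
ica_adjustment <- function(triple, n) {
  r <- as_triple_vector(triple)
  if (n <= 0) stopf("n must be > 0")
  if (r[3] >= r[1])
    stopf("no real solution: r_eca >= r_cca")
  r_adj <- (r[1]^n - r[3]^n)^(1 / n)
  100 * (r_adj - r[2]) / r[2]
}

#' Radius-ratio and area-ratio summary of a cohort
#'
#' Per-record ratios ICA/CCA, ECA/CCA, ECA/ICA and the bifurcation area
#' ratio under two definitions -- (i) the daughter-to-parent
#' cross-sectional area ratio \eqn{(r_{ICA}^2 + r_{ECA}^2)/r_{CCA}^2}
#' and (ii) the radius-sum ratio \eqn{(r_{ICA} + r_{ECA})/r_{CCA}} --
#' summarised as the mean and SD across records (mean of ratios, not
#' ratio of means).
#'
#' @param records data.frame of radius triples (>= 1 row).
#' @return data.frame of class `ratio_summary` with columns `quantity`,
#'   `mean`, `sd`.
#' @examples
#' summarize_ratios(data.frame(r_cca_mm = 1, r_ica_mm = 0.67,
#'                             r_eca_mm = 0.61))
#' @export
summarize_ratios <- function(records) {
  tr <- get_triples(records)
  if (!nrow(tr)) stopf("need at least one record")
  rat <- data.frame(
    ica_cca = tr$r_ica / tr$r_cca,
    eca_cca = tr$r_eca / tr$r_cca,
    eca_ica = tr$r_eca / tr$r_ica,
    area_ratio_sq = (tr$r_ica^2 + tr$r_eca^2) / tr$r_cca^2,
    area_ratio_sum = (tr$r_ica + tr$r_eca) / tr$r_cca)
  lab <- c(ica_cca = "ICA/CCA", eca_cca = "ECA/CCA", eca_ica = "ECA/ICA",
           area_ratio_sq = "area ratio (i) (r_ica^2+r_eca^2)/r_cca^2",
           area_ratio_sum = "area ratio (ii) (r_ica+r_eca)/r_cca")
  out <- data.frame(quantity = unname(lab[names(rat)]),
                    mean = vapply(rat, mean, numeric(1)),
                    sd = vapply(rat, function(x)
                      if (length(x) > 1) sd(x) else 0, numeric(1)),
                    row.names = names(rat))
  class(out) <- c("ratio_summary", "data.frame")
  out
}

#' Paired left/right comparison
#'
#' Paired t-tests of left versus right ICA radii and left versus right
#' per-bifurcation exponents, over subjects contributing both sides
#' (rows with an unsolvable exponent, or subjects missing a side, are
#' excluded and counted). Degenerate cases are handled explicitly:
#' all-zero paired differences give t = 0, p = 1; a constant nonzero
#' difference gives |t| = Inf, p = 0.
#'
#' @param records data.frame with `subject_id`, `side` ("left"/"right"),
#'   radius columns and (optionally precomputed) `n`.
#' @return data.frame of class `side_comparison` with one row per
#'   quantity (`ica_radius`, `exponent`): columns `t`, `df`, `p`,
#'   `n_pairs`, `n_excluded_subjects`.
#' @export
compare_sides <- function(records) {
  if (!all(c("subject_id", "side") %in% names(records)))
    stopf("records must contain subject_id and side columns")
  if (!"n" %in% names(records)) records <- add_exponents(records)
  tr <- get_triples(records)
  records$.ica <- tr$r_ica

  paired <- function(value_col, use) {
    df <- records[use, c("subject_id", "side", value_col)]
    wide <- merge(df[df$side == "left", c("subject_id", value_col)],
                  df[df$side == "right", c("subject_id", value_col)],
                  by = "subject_id", suffixes = c("_left", "_right"))
    n_excl <- length(unique(records$subject_id)) - nrow(wide)
    d <- wide[[paste0(value_col, "_left")]] -
      wide[[paste0(value_col, "_right")]]
    np <- length(d)
    if (np < 2)
      stopf("need at least 2 subjects with both sides (have %d)", np)
    sdd <- sd(d)
    if (sdd == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      t <- mean(d) / (sdd / sqrt(np))
      p <- 2 * pt(-abs(t), df = np - 1)
    }
    data.frame(t = t, df = np - 1, p = p, n_pairs = np,
               n_excluded_subjects = n_excl)
  }

  out <- rbind(cbind(quantity = "ica_radius",
                     paired(".ica", rep(TRUE, nrow(records)))),
               cbind(quantity = "exponent",
                     paired("n", records$solve_status == "ok")))
  class(out) <- c("side_comparison", "data.frame")
  out
}

#' Restrict a cohort to low-tortuosity bifurcations
#'
#' Keeps records whose ICA tortuosity is strictly below the threshold
#' (default 0.1, the conventional cutoff for "straight" arteries under
#' the Murray model assumptions). Records with missing tortuosity are
#' dropped.
#'
#' @param records data.frame with an `ica_tortuosity` column.
#' @param threshold strict upper bound on tortuosity.
#' @return the filtered records.
#' @export
filter_low_tortuosity <- function(records, threshold = 0.1) {
  if (!"ica_tortuosity" %in% names(records))
    stopf("records must contain an ica_tortuosity column")
  if (threshold <= 0) stopf("threshold must be > 0")
  keep <- !is.na(records$ica_tortuosity) &
    records$ica_tortuosity < threshold
  records[keep, , drop = FALSE]
}
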