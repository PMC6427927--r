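# Synthetic two-group cohort generator: block-structured (lobe-wise)
# regional correlation with bridging hub regions, AR(1)-coloured Gaussian
# time series, and attenuated between-block/hub coupling in the case group.

#' Specification of a synthetic cohort
#'
#' Defines the ground-truth structure of a simulated two-group cohort. The
#' defaults mirror the reference study scale: 39 control and 41 case
#' subjects, 116 regions observed for 193 timepoints, eight contiguous
#' lobe-sized correlation blocks, four hub regions bridging the blocks, and
#' case-group attenuation of the between-block and hub couplings.
#'
#' @param n_control,n_case Subjects per group.
#' @param n_regions Number of regions.
#' @param n_timepoints Timepoints per series.
#' @param block_sizes Sizes of the contiguous correlation blocks; must sum
#'   to `n_regions`.
#' @param hub_regions Region indices acting as connector hubs.
#' @param rho_within Within-block correlation, in (0, 1).
#' @param rho_between Between-block correlation, in `[0, rho_within)`.
#' @param rho_hub Correlation of hub regions with regions outside their own
#'   block.
#' @param case_attenuation Factor in `[0, 1]` multiplying between-block and
#'   hub correlations in the case group (1 = no group difference).
#' @param ar1_coef Temporal AR(1) coefficient in `[0, 1)`.
#' @param age_mean,age_sd Age distribution (Normal, truncated positive).
#' @param p_male_control,p_male_case Probability that a subject is male.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_control = 39L, n_case = 41L,
                           n_regions = 116L, n_timepoints = 193L,
                           block_sizes = c(30L, 2L, 12L, 12L, 12L, 8L, 14L, 26L),
                           hub_regions = c(47L, 54L, 67L, 99L),
                           rho_within = 0.5, rho_between = 0.15,
                           rho_hub = 0.25, case_attenuation = 0.5,
                           ar1_coef = 0.4,
                           age_mean = 65, age_sd = 7,
                           p_male_control = 0.5, p_male_case = 0.5,
                           seed = 1L) {
  stopifnot(n_control >= 1, n_case >= 1, all(block_sizes >= 1),
            sum(block_sizes) == n_regions,
            rho_within > 0, rho_within < 1,
            rho_between >= 0, rho_between < rho_within,
            rho_hub >= 0, rho_hub < 1,
            case_attenuation >= 0, case_attenuation <= 1,
            ar1_coef >= 0, ar1_coef < 1,
            all(hub_regions >= 1), all(hub_regions <= n_regions))
  structure(list(n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 block_sizes = as.integer(block_sizes),
                 hub_regions = as.integer(hub_regions),
                 rho_within = rho_within, rho_between = rho_between,
                 rho_hub = rho_hub, case_attenuation = case_attenuation,
                 ar1_coef = ar1_coef, age_mean = age_mean, age_sd = age_sd,
                 p_male_control = p_male_control, p_male_case = p_male_case,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Ground-truth regional covariance of one group
#'
#' Builds the unit-diagonal correlation (= covariance) matrix implied by
#' the spec: `rho_within` inside the contiguous blocks, `rho_between`
#' across blocks, `rho_hub` on hub rows/columns outside the hub's own
#' block; in the case group the between-block and hub entries are
#' multiplied by `case_attenuation`. If the result is not positive
#' definite, a diagonal jitter is applied (and reported via a message)
#' before rescaling back to unit diagonal.
#'
#' @param spec A `synthetic_spec`.
#' @param group `"control"` or `"case"`.
#' @return The regions x regions covariance matrix.
#' @export
build_group_covariance <- function(spec, group = c("control", "case")) {
  group <- match.arg(group)
  n <- spec$n_regions
  block <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  same_block <- outer(block, block, "==")
  sigma <- ifelse(same_block, spec$rho_within, spec$rho_between)
  is_hub <- seq_len(n) %in% spec$hub_regions
  hub_off <- (outer(is_hub, rep(TRUE, n), "&") |
              outer(rep(TRUE, n), is_hub, "&")) & !same_block
  sigma[hub_off] <- spec$rho_hub
  if (group == "case") {
    att <- !same_block
    sigma[att] <- sigma[att] * spec$case_attenuation
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    jitter <- abs(min(ev)) + 1e-8
    message(sprintf("covariance not positive definite; adding diagonal jitter %.3g",
                    jitter))
    sigma <- sigma + diag(jitter, n)
    sigma <- stats::cov2cor(sigma)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance not positive definite after jitter")
  }
  sigma
}

#' Generate a synthetic two-group cohort
#'
#' Draws, for every subject, a zero-mean Gaussian regional time series with
#' the group covariance, colours it temporally with an AR(1) recursion
#' driven by the spatially correlated innovations, and re-standardises each
#' region to unit sample variance (which preserves the designed
#' cross-correlations in expectation). Ages are Normal (truncated positive)
#' and sexes Bernoulli per the spec. The whole cohort is a deterministic
#' function of `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @return List of class `synthetic_cohort` with `manifest` (subject_id,
#'   group, age, sex), `series` (named list of `fc_timeseries`), and the
#'   ground-truth covariances `sigma_control`, `sigma_case`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sig <- list(control = build_group_covariance(spec, "control"),
              case = build_group_covariance(spec, "case"))
  chol_s <- lapply(sig, chol)
  set.seed(spec$seed)
  groups <- c(rep("control", spec$n_control), rep("case", spec$n_case))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "ctrl", "case"),
                 c(seq_len(spec$n_control), seq_len(spec$n_case)))
  phi <- spec$ar1_coef
  series <- vector("list", length(ids))
  age <- numeric(length(ids)); sex <- character(length(ids))
  for (s in seq_along(ids)) {
    g <- groups[s]
    z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_regions),
                spec$n_timepoints, spec$n_regions) %*% chol_s[[g]]
    if (phi > 0) {
      innov_sd <- sqrt(1 - phi^2)
      x <- apply(z, 2, function(col)
        as.numeric(stats::filter(innov_sd * col, phi, method = "recursive",
                                 init = col[1])))
    } else x <- z
    sds <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, sds, "/")
    series[[s]] <- as_fc_timeseries(x, tr_seconds = 2.5)
    repeat {
      age[s] <- stats::rnorm(1, spec$age_mean, spec$age_sd)
      if (age[s] > 0) break
    }
    p_male <- if (g == "control") spec$p_male_control else spec$p_male_case
    sex[s] <- if (stats::runif(1) < p_male) "M" else "F"
  }
  names(series) <- ids
  manifest <- data.frame(subject_id = ids, group = groups,
                         age = round(age, 1), sex = sex,
                         stringsAsFactors = FALSE)
  structure(list(manifest = manifest, series = series,
                 sigma_control = sig$control, sigma_case = sig$case,
                 spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes `manifest.csv` (with a `timeseries_path` column), one
#' tab-separated time-series file per subject, and the two ground-truth
#' covariance matrices, so a cohort can be re-read through the standard
#' readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$timeseries_path <- paste0(man$subject_id, ".tsv")
  for (s in seq_len(nrow(man))) {
    utils::write.table(unclass(cohort$series[[man$subject_id[s]]]),
                       file.path(dir, man$timeseries_path[s]),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_matrix_csv(cohort$sigma_control, file.path(dir, "sigma_control.csv"))
  write_matrix_csv(cohort$sigma_case, file.path(dir, "sigma_case.csv"))
  invisible(dir)
}
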