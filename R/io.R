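#' Read trial summaries from a flat CSV file
#'
#' Expects columns `arm` (0 = control, 1..k experimental), `stage` (1 or
#' 2), `mean`, `n`. Stage 1 must cover all `k + 1` arms with a common `n`;
#' stage 2, if present, must contain exactly the control and the selected
#' arm with a common `n`. The outcome SD and futility boundary are not
#' part of the data and must be supplied.
#'
#' @param path CSV file path.
#' @param sigma Known common outcome SD.
#' @param b Futility boundary (default `-Inf`, no gate).
#' @return An `"asd_trial"`.
#' @export
read_trial_csv <- function(path, sigma, b = -Inf) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("arm", "stage", "mean", "n")
  if (!all(need %in% names(df)))
    stop("trial CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  s1 <- df[df$stage == 1L, ]
  s2 <- df[df$stage == 2L, ]
  s1 <- s1[order(s1$arm), ]
  k <- nrow(s1) - 1L
  if (k < 1L || !isTRUE(all(sort(s1$arm) == 0:k)))
    stop("stage 1 must contain arms 0..k exactly once each", call. = FALSE)
  if (length(unique(s1$n)) != 1L)
    stop("unequal stage-1 allocation in 'n'; the design assumes equal per-arm allocation",
         call. = FALSE)
  design <- asd_design(k = k, n1 = s1$n[1L],
                       n2 = if (nrow(s2)) unique(s2$n)[1L] else s1$n[1L],
                       sigma = sigma, b = b)
  if (nrow(s2) == 0L) {
    tr <- select_and_gate(s1$mean, design)
    if (tr$continued)
      stop("data imply the trial continued but no stage-2 rows are present", call. = FALSE)
    return(asd_trial(s1$mean, design = design))
  }
  if (length(unique(s2$n)) != 1L)
    stop("unequal stage-2 allocation in 'n'", call. = FALSE)
  sel <- select_and_gate(s1$mean, design)
  if (!setequal(s2$arm, c(0L, sel$S)))
    stop(sprintf("stage 2 must contain the control and the selected arm (%d)", sel$S),
         call. = FALSE)
  asd_trial(s1$mean, y0 = s2$mean[s2$arm == 0L],
            yS = s2$mean[s2$arm == sel$S], design = design)
}

#' Write trial summaries to a flat CSV file
#'
#' Inverse of [read_trial_csv()] (comma-separated, UTF-8, header row,
#' `.` decimal separator).
#'
#' @param trial An `"asd_trial"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "asd_trial"))
  k <- trial$design$k
  df <- data.frame(arm = 0:k, stage = 1L, mean = trial$x, n = trial$design$n1)
  if (trial$continued)
    df <- rbind(df, data.frame(arm = c(0L, trial$S), stage = 2L,
                               mean = c(trial$y0, trial$yS), n = trial$design$n2))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse a trial configuration file (YAML or JSON)
#'
#' Reads a config block of the form
#' ```
#' k: 3
#' n1: 71
#' n2: 71
#' sigma: 6
#' b: 0
#' stage1_means: [-0.082, 0.413, 1.766, 1.567]
#' stage2_means: {control: 0.049, selected: 1.451}
#' ```
#' Unknown keys are rejected with the offending name. Omitting `b`
#' defaults to `-Inf` (no futility gate) and is reported with a message.
#' `stage2_means` may be omitted for a trial that stopped at stage 1.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `"asd_trial"`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  allowed <- c("k", "n1", "n2", "sigma", "b", "stage1_means", "stage2_means")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  for (key in c("k", "n1", "n2", "sigma", "stage1_means"))
    if (is.null(cfg[[key]])) stop("config key missing: ", key, call. = FALSE)
  if (is.null(cfg$b)) {
    message("config: 'b' not given; using b = -Inf (no futility gate)")
    cfg$b <- -Inf
  }
  design <- asd_design(k = cfg$k, n1 = cfg$n1, n2 = cfg$n2,
                       sigma = cfg$sigma, b = cfg$b)
  if (length(cfg$stage1_means) != design$k + 1L)
    stop(sprintf("'stage1_means' must have k + 1 = %d entries", design$k + 1L),
         call. = FALSE)
  if (is.null(cfg$stage2_means))
    return(asd_trial(as.numeric(cfg$stage1_means), design = design))
  sm <- cfg$stage2_means
  if (!setequal(names(sm), c("control", "selected")))
    stop("'stage2_means' must have exactly the keys 'control' and 'selected'",
         call. = FALSE)
  asd_trial(as.numeric(cfg$stage1_means), y0 = sm$control, yS = sm$selected,
            design = design)
}

#' Write a trial configuration file
#'
#' Inverse of [parse_config()]; format chosen from the file extension.
#'
#' @param trial An `"asd_trial"`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(trial, path) {
  stopifnot(inherits(trial, "asd_trial"))
  des <- trial$design
  cfg <- list(k = des$k, n1 = des$n1, n2 = des$n2, sigma = des$sigma,
              b = des$b, stage1_means = trial$x)
  if (trial$continued)
    cfg$stage2_means <- list(control = trial$y0, selected = trial$yS)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Packaged worked-example trial (generalized anxiety disorder case study)
#'
#' The packaged reference trial: three doses of an experimental drug for
#' generalized anxiety disorder against placebo, primary endpoint the
#' 8-week change in Hamilton Rating Scale for Anxiety total score, assumed
#' normal with known SD 6 points; `n1 = n2 = 71` per arm (`t = 0.5`) and
#' futility boundary 0 on the stage-1 dose-minus-placebo difference. Dose
#' 2 is selected at the interim and the trial continues.
#'
#' @return An `"asd_trial"`.
#' @examples
#' load_table1()
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_trial.csv", package = "seamest",
                      mustWork = TRUE)
  read_trial_csv(path, sigma = 6, b = 0)
}

#' Run the packaged worked example
#'
#' Loads the packaged case-study trial ([load_table1()]), computes all
#' four difference estimates and their components, and prints them. The
#' computation is deterministic.
#'
#' @param solver An [solver_config()].
#' @return The `"asd_estimates"` object, invisibly.
#' @export
run_example <- function(solver = solver_config()) {
  est <- estimate_all(load_table1(), solver)
  print(est)
  invisible(est)
}
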