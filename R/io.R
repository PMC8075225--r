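#' Read a study table
#'
#' Reads the flat per-bird CSV layout: identity columns (`bird_id`,
#' `nest_id`, `species`, `sex`, optionally `stratum`), the 13 brood and
#' environmental indicator columns, mass columns `mass_d<day>` for the odd
#' weighing days, and (optionally) a previously written fitted-parameter
#' block (`fit_*` columns).  Rows violating the invariants (non-positive
#' masses, unknown species/sex, duplicate bird ids) are rejected with
#' row-numbered messages.  A logical `selected` column flags birds passing
#' the study's selection filters where the metadata to evaluate them is
#' present (`first_brood`, `fledged`, complete weighings, known sex);
#' failing rows are retained and flagged, not dropped.
#'
#' @param path CSV file path.
#' @return Data frame of class `study_table` with attribute `mass_days`.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_table(tab)
}

#' Validate a study table held in memory
#'
#' @param tab data frame in the study-table layout.
#' @return The validated table (class `study_table`), with invalid rows
#'   removed (each removal is messaged with its row number).
#' @export
validate_study_table <- function(tab) {
  mandatory <- c("bird_id", "nest_id", "species", "sex")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols) > 0)
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  mass_cols <- grep("^mass_d[0-9]+$", names(tab), value = TRUE)
  if (length(mass_cols) == 0) stop("missing mandatory columns: mass_d<day>")
  days <- sort(as.integer(sub("^mass_d", "", mass_cols)))
  mass_cols <- paste0("mass_d", days)

  bad <- rep(FALSE, nrow(tab))
  note <- function(rows, why) {
    if (length(rows) > 0) {
      warning("rejecting row(s) ", paste(rows, collapse = ", "), ": ", why,
              call. = FALSE)
      bad[rows] <<- TRUE
    }
  }
  note(which(duplicated(tab$bird_id)), "duplicate bird_id")
  note(which(!tab$species %in% c("blue tit", "great tit")),
       "species must be 'blue tit' or 'great tit'")
  note(which(!tab$sex %in% c("female", "male")),
       "sex must be 'female' or 'male'")
  m <- as.matrix(tab[, mass_cols])
  note(which(apply(m, 1, function(x)
    any(!is.na(x) & (!is.finite(x) | x <= 0)))),
    "non-positive mass")
  tab <- tab[!bad, , drop = FALSE]

  if (!"stratum" %in% names(tab))
    tab$stratum <- paste0(ifelse(tab$species == "blue tit", "blue", "great"),
                          "_", ifelse(tab$sex == "female", "f", "m"))
  complete <- stats::complete.cases(tab[, mass_cols])
  sel <- complete
  if ("first_brood" %in% names(tab)) sel <- sel & as.logical(tab$first_brood)
  if ("fledged" %in% names(tab)) sel <- sel & as.logical(tab$fledged)
  tab$selected <- sel
  rownames(tab) <- NULL
  attr(tab, "mass_days") <- days
  class(tab) <- c("study_table", class(tab))
  tab
}

#' Extract one bird's mass series from a study table
#'
#' Maps weighing day `d` to model time `t = d - 1` (the first weighing
#' defines `t = 0`).
#'
#' @param tab a `study_table`.
#' @param bird_id bird identifier.
#' @return A [mass_series()].
#' @export
bird_mass_series <- function(tab, bird_id) {
  days <- attr(tab, "mass_days")
  if (is.null(days))
    days <- sort(as.integer(sub("^mass_d", "",
                                grep("^mass_d[0-9]+$", names(tab),
                                     value = TRUE))))
  i <- match(bird_id, tab$bird_id)
  if (is.na(i)) stop("unknown bird_id: ", bird_id)
  m <- as.numeric(tab[i, paste0("mass_d", days)])
  keep <- !is.na(m)
  mass_series(days[keep] - 1, m[keep])
}

#' Fit every bird in a study table
#'
#' Runs the grid search for each (selected) bird and collects the best-fit
#' parameters, goodness of fit, and shape parameters into one table.  Per-bird
#' seeds are derived from the master seed so the run is reproducible end to
#' end.
#'
#' @param tab a `study_table` (see [read_study_table()] /
#'   [validate_study_table()]).
#' @param grid a [bp_grid()].
#' @param config a [bp_anneal_config()].
#' @param seed master integer seed.
#' @param gfr_threshold RL-squared threshold at which a good-fit-region
#'   median ratio is recorded per bird (`NA` when the region is empty).
#' @param keep_fits if `TRUE`, the full `bp_fit` objects (including grid
#'   diagnostics) are attached as attribute `fits`.
#' @param only_selected fit only rows with `selected == TRUE`.
#' @return Data frame with one row per fitted bird: `bird_id`, best-fit
#'   `a, b, c, p, q`, `ssle`, `rl2`, `aicc`, `m_max`, `m_infl`, `t_infl`,
#'   `ratio`, `sigmoidal`, `near_diagonal`, `boundary_hit`,
#'   `points_evaluated`, `gfr_median_ratio`.
#' @export
fit_study <- function(tab, grid = bp_grid(), config = bp_anneal_config(),
                      seed = 1, gfr_threshold = 0.995, keep_fits = FALSE,
                      only_selected = TRUE) {
  stopifnot(is.data.frame(tab))
  rows <- if (only_selected && "selected" %in% names(tab))
    which(tab$selected) else seq_len(nrow(tab))
  fits <- list()
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    id <- tab$bird_id[rows[k]]
    series <- bird_mass_series(tab, id)
    fit <- bp_grid_search(series, grid, config,
                          seed = (seed + k) %% .Machine$integer.max)
    gfr_med <- tryCatch(good_fit_region(fit, gfr_threshold)$ratio_median,
                        error = function(e) NA_real_)
    p <- fit$params
    out[[k]] <- data.frame(
      bird_id = id, a = p$a, b = p$b, c = p$c, p = p$p, q = p$q,
      ssle = fit$ssle, rl2 = fit$rl2, aicc = fit$aicc,
      m_max = fit$shape$m_max, m_infl = fit$shape$m_infl,
      t_infl = fit$shape$t_infl, ratio = fit$shape$ratio,
      sigmoidal = p$a > 0, near_diagonal = bp_is_near_diagonal(p$a, p$b),
      boundary_hit = fit$boundary_hit,
      points_evaluated = fit$points_evaluated,
      gfr_median_ratio = gfr_med)
    if (keep_fits) fits[[id]] <- fit
  }
  res <- do.call(rbind, out)
  if (keep_fits) attr(res, "fits") <- fits
  res
}

#' Analyze fitted ratios against the nest indicators
#'
#' Joins a fit table onto the study table and runs the three-test battery
#' for every stratum and indicator, plus the reliability rule and the
#' per-stratum sign tests of the sigmoidal birds' ratios against 1/3.
#'
#' @param tab a `study_table`.
#' @param fits a [fit_study()] result (or any data frame with `bird_id` and
#'   `ratio`).
#' @param indicators indicator columns to test (default: all 13).
#' @param ratio_threshold high-ratio cutoff for test c.
#' @param alpha,alpha_high significance thresholds for the reliability rule.
#' @return List with `battery` (see [run_test_battery()]), `verdicts`
#'   (see [reliability_verdict()]), `sign_tests` (per-stratum sign test of
#'   sigmoidal ratios vs 1/3), and `birds` (the joined analysis table).
#' @export
analyze_study <- function(tab, fits, indicators = nest_indicator_names(),
                          ratio_threshold = 0.5, alpha = 0.05,
                          alpha_high = 0.01) {
  stopifnot(all(c("bird_id", "ratio") %in% names(fits)))
  keep <- intersect(c("bird_id", "nest_id", "stratum", indicators),
                    names(tab))
  birds <- merge(as.data.frame(tab)[, keep],
                 fits[, intersect(c("bird_id", "ratio", "sigmoidal"),
                                  names(fits))],
                 by = "bird_id")
  battery <- run_test_battery(birds, indicators, ratio_threshold)
  verdicts <- reliability_verdict(battery, alpha, alpha_high)
  sign_tests <- lapply(split(birds, birds$stratum), function(d) {
    r <- if ("sigmoidal" %in% names(d)) d$ratio[d$sigmoidal] else
      d$ratio[d$ratio > 0]
    if (length(r) < 5) return(NULL)
    sign_test_vs_value(r, 1 / 3, alternative = "greater")
  })
  list(battery = battery, verdicts = verdicts,
       sign_tests = sign_tests[!vapply(sign_tests, is.null, logical(1))],
       birds = birds)
}

#' Write a study table, fits, and battery report
#'
#' Appends the fitted-parameter block (`fit_` columns) to the study table and
#' writes it as CSV, together with an optional battery report CSV and a
#' plain-text run-metadata file (seed, configuration summary, package
#' version).  Outputs are plain text and byte-stable for a fixed seed and
#' configuration.
#'
#' @param tab a `study_table`.
#' @param fits a [fit_study()] result; must match the table's bird ids.
#' @param battery optional [run_test_battery()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param metadata optional named list written into the metadata file.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tab, fits, battery = NULL, dir = ".",
                          prefix = "study", metadata = list()) {
  stopifnot(is.data.frame(tab), is.data.frame(fits))
  if (!all(fits$bird_id %in% tab$bird_id))
    stop("fit table contains bird ids absent from the study table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit_block <- fits[, c("bird_id", "a", "b", "c", "p", "q", "ssle", "rl2",
                        "ratio")]
  names(fit_block)[-1] <- paste0("fit_", names(fit_block)[-1])
  out <- merge(as.data.frame(tab), fit_block, by = "bird_id",
               all.x = TRUE, sort = FALSE)
  out <- out[order(out$bird_id), ]
  table_path <- file.path(dir, paste0(prefix, "_table.csv"))
  utils::write.csv(out, table_path, row.names = FALSE)
  paths <- table_path
  if (!is.null(battery)) {
    battery_path <- file.path(dir, paste0(prefix, "_battery.csv"))
    utils::write.csv(as.data.frame(battery), battery_path, row.names = FALSE)
    paths <- c(paths, battery_path)
  } else if (nrow(fits) > 0) {
    warning("no battery supplied; writing table only")
  }
  meta_path <- file.path(dir, paste0(prefix, "_metadata.txt"))
  meta <- c(sprintf("bpgrowth %s",
                    as.character(utils::packageVersion("bpgrowth"))),
            vapply(names(metadata), function(k)
              paste0(k, ": ", paste(format(metadata[[k]]), collapse = " ")),
              character(1)))
  writeLines(meta, meta_path)
  invisible(c(paths, meta_path))
}

#' Write a simulated study to CSV
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written (study table and truth table).
#' @export
write_simulation <- function(sim, dir = ".", prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table_path <- file.path(dir, paste0(prefix, "_table.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(sim$table, table_path, row.names = FALSE)
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(c(table_path, truth_path))
}
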