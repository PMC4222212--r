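#' Run the full introgression-quantification pipeline
#'
#' Executes the five-step workflow on one genotype input:
#' 1. split the input into wild references, farm references and admixed
#'    query samples according to `roles`;
#' 2. build the wild and farm center points (equal subsampling within each
#'    group, then frequency-conditional random mating);
#' 3. assign every reference individual, one by one, to the center points
#'    and build the wild and farm P(wild) reference distributions;
#' 4. assign the admixed individuals the same way;
#' 5. test the admixed sample for introgression (without-reference mode,
#'    plus with-reference mode when `historical` names a wild population)
#'    and estimate the proportion of wild genome left with a bootstrap CI.
#'
#' @param genotypes a [genotype_matrix()] or path to a STRUCTURE-style
#'   (`.str`/`.txt`) or CSV dosage file.
#' @param roles named list with character vectors `wild_ref`, `farm_ref`,
#'   `admixed`: population labels for each role. Every label must exist in
#'   the input.
#' @param settings an [mcmc_settings()]; its seed also seeds subsampling,
#'   synthesis and the bootstrap.
#' @param mode assignment mode, `"mcmc"` or `"ml"` (see [assign_batch()]).
#' @param n_per_pop equal subsample size per reference population (`NULL` =
#'   smallest population within each group).
#' @param n_centerpoint synthetic individuals per center point (default 100).
#' @param historical optional wild population label to use as a
#'   population-specific historical reference in the test.
#' @param n_boot bootstrap replicates for the wild-genome CI.
#' @param out_dir optional directory; when given, per-individual results
#'   (CSV), the JSON report and a plain-text summary are written there.
#' @param level one-sided test level and CI coverage complement (0.05).
#' @param verbose print per-stage progress (default TRUE).
#' @return a `pipeline_report` list with elements `config`, `center_points`,
#'   `results` (per-individual data frame), `distributions` (wild, farm,
#'   admixed), `test_without_reference`, `test_with_reference` (NULL unless
#'   `historical` given), `estimate`, `timings`.
#' @export
run_pipeline <- function(genotypes, roles, settings = mcmc_settings(),
                         mode = c("mcmc", "ml"), n_per_pop = NULL,
                         n_centerpoint = 100L, historical = NULL,
                         n_boot = 1000L, out_dir = NULL, level = 0.05,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
    if (verbose) message(sprintf("[introquant] %s done (%.1fs)",
                                 stage, timings[[stage]]))
  }

  if (is.character(genotypes)) {
    genotypes <- if (grepl("\\.csv$", genotypes, ignore.case = TRUE)) {
      read_genotype_csv(genotypes)
    } else read_structure_file(genotypes)
  }
  for (nm in c("wild_ref", "farm_ref", "admixed")) {
    if (is.null(roles[[nm]])) stop("roles$", nm, " is required")
    absent <- setdiff(roles[[nm]], populations(genotypes))
    if (length(absent)) {
      stop("roles$", nm, " names populations absent from the input: ",
           paste(absent, collapse = ", "))
    }
  }
  if (!is.null(historical) && !(historical %in% roles$wild_ref)) {
    stop("historical must be one of roles$wild_ref")
  }
  tick("validate")

  wild_pool <- subsample_equal(genotypes, roles$wild_ref, n_per_pop,
                               seed = settings$seed + 101L)
  farm_pool <- subsample_equal(genotypes, roles$farm_ref, n_per_pop,
                               seed = settings$seed + 102L)
  wild_cp <- synthesize_centerpoint(wild_pool, "wild", n_centerpoint,
                                    seed = settings$seed + 103L)
  farm_cp <- synthesize_centerpoint(farm_pool, "farm", n_centerpoint,
                                    seed = settings$seed + 104L)
  tick("center_points")

  pops <- populations(genotypes)
  ref_wild <- subset_individuals(genotypes, pops %in% roles$wild_ref)
  ref_farm <- subset_individuals(genotypes, pops %in% roles$farm_ref)
  adm <- subset_individuals(genotypes, pops %in% roles$admixed)

  s <- settings
  res_wild <- assign_batch(ref_wild, wild_cp, farm_cp, s, mode = mode)
  s$seed <- settings$seed + 200000L
  res_farm <- assign_batch(ref_farm, wild_cp, farm_cp, s, mode = mode)
  dist_wild <- build_reference_distribution(res_wild, role = "wild")
  dist_farm <- build_reference_distribution(res_farm, role = "farm")
  tick("reference_distributions")

  s$seed <- settings$seed + 400000L
  res_adm <- assign_batch(adm, wild_cp, farm_cp, s, mode = mode)
  dist_adm <- build_reference_distribution(res_adm, role = "admixed")
  tick("admixed_assignment")

  wild_panel <- list(dist_wild)
  test_wo <- if (length(roles$wild_ref) >= 2L) {
    test_mean_pwild(dist_adm, historical = NULL, wild_panel = wild_panel,
                    level = level)
  } else NULL
  test_w <- NULL
  if (!is.null(historical)) {
    hist_dist <- build_reference_distribution(
      res_wild[res_wild$population == historical, , drop = FALSE],
      role = "wild")
    test_w <- test_mean_pwild(dist_adm, historical = hist_dist,
                              wild_panel = wild_panel, level = level)
  }
  estimate <- bootstrap_ci(dist_adm$values$p_wild,
                           wild_ref = dist_wild$mean,
                           farm_ref = dist_farm$mean,
                           n_boot = n_boot, level = 0.95,
                           seed = settings$seed + 500000L)
  tick("tests_and_estimate")

  results <- rbind(
    cbind(res_wild, role = "wild_ref"),
    cbind(res_farm, role = "farm_ref"),
    cbind(res_adm, role = "admixed")
  )
  report <- structure(list(
    config = list(roles = roles, settings = unclass(settings), mode = mode,
                  n_per_pop = n_per_pop, n_centerpoint = n_centerpoint,
                  historical = historical, n_boot = n_boot, level = level),
    center_points = list(wild = wild_cp, farm = farm_cp),
    results = results,
    distributions = list(wild = dist_wild, farm = dist_farm,
                         admixed = dist_adm),
    test_without_reference = test_wo,
    test_with_reference = test_w,
    estimate = estimate,
    timings = timings
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("introquant pipeline report\n")
  cat(sprintf("  wild reference:  mean P(wild) %.3f (5th pct %.3f, n = %d)\n",
              x$distributions$wild$mean, x$distributions$wild$percentile_5,
              x$distributions$wild$n))
  cat(sprintf("  farm reference:  mean P(wild) %.3f (95th pct %.3f, n = %d)\n",
              x$distributions$farm$mean, x$distributions$farm$percentile_95,
              x$distributions$farm$n))
  cat(sprintf("  admixed sample:  mean P(wild) %.3f (n = %d)\n",
              x$distributions$admixed$mean, x$distributions$admixed$n))
  if (!is.null(x$test_without_reference)) print(x$test_without_reference)
  if (!is.null(x$test_with_reference)) print(x$test_with_reference)
  print(x$estimate)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `results.csv` (per-individual P(wild)), `report.json` (config,
#' distribution summaries, tests, estimate) and `summary.txt` (the printed
#' report) into `out_dir`.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  dist_summary <- function(d) {
    list(role = d$role, n = d$n, mean = d$mean,
         percentile_5 = d$percentile_5, percentile_95 = d$percentile_95,
         per_population_means = as.list(d$per_population_means))
  }
  test_summary <- function(t) {
    if (is.null(t)) return(NULL)
    t[c("mode", "reference_mean_logit", "contemporary_mean_logit",
        "sigma2_within", "sigma2_between", "n_contemporary", "n_reference",
        "critical_value_logit", "critical_value", "p_value", "reject",
        "level")]
  }
  json <- list(
    config = report$config,
    distributions = lapply(report$distributions, dist_summary),
    test_without_reference = test_summary(report$test_without_reference),
    test_with_reference = test_summary(report$test_with_reference),
    estimate = unclass(report$estimate),
    timings = as.list(report$timings)
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  con <- file(file.path(out_dir, "summary.txt"), "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(out_dir)
}
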