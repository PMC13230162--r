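#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with the study's
#' values as defaults, so any deviation is explicit in the manifest:
#' coverage gate 1x, abundance presence rule 1e-5, prevalence 10% for
#' set analysis and 5% for enrichment, 999 permutations, 1,000 bootstrap
#' iterations, age-stage boundaries 365/1095 days, minimum group size 10.
#'
#' @param input_dir directory with abundance/coverage/metadata TSVs (may
#'   be NULL when a cohort object is passed to [runAll()] directly)
#' @param output_dir directory for result files
#' @param seed integer seed (mandatory) driving every random stage
#' @param coverage_threshold effective-coverage presence gate
#' @param abund_threshold relative-abundance presence rule
#' @param set_prevalence prevalence cutoff of the shared-taxa analysis
#' @param enrichment_prevalence,enrichment_min_mean enrichment filters
#' @param permutations PERMANOVA permutations
#' @param bootstrap_iterations resampling iterations
#' @param inner_permutations PERMANOVA permutations inside the beta
#'   bootstrap
#' @param min_group_size smallest factor-level size kept in stratified
#'   models
#' @param read_length average read length in bp
#' @return validated `runConfig` list
#' @export
runConfig <- function(output_dir, seed, input_dir = NULL,
                      coverage_threshold = 1, abund_threshold = 1e-5,
                      set_prevalence = 0.10, enrichment_prevalence = 0.05,
                      enrichment_min_mean = 1e-5, permutations = 999L,
                      bootstrap_iterations = 1000L,
                      inner_permutations = 999L, min_group_size = 10L,
                      read_length = 151L) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  chk <- function(x, lo, hi, what)
    if (!is.numeric(x) || x < lo || x > hi)
      stop(sprintf("%s must lie in [%g, %g]", what, lo, hi))
  chk(coverage_threshold, 0, Inf, "coverage_threshold")
  chk(abund_threshold, 1e-12, 0.999999, "abund_threshold")
  chk(set_prevalence, 0, 1, "set_prevalence")
  chk(enrichment_prevalence, 0, 1, "enrichment_prevalence")
  chk(enrichment_min_mean, 0, 1, "enrichment_min_mean")
  chk(permutations, 0, Inf, "permutations")
  chk(bootstrap_iterations, 1, Inf, "bootstrap_iterations")
  chk(inner_permutations, 1, Inf, "inner_permutations")
  chk(min_group_size, 1, Inf, "min_group_size")
  chk(read_length, 1, Inf, "read_length")
  structure(list(
    input_dir = input_dir, output_dir = output_dir,
    seed = as.integer(seed),
    coverage_threshold = coverage_threshold,
    abund_threshold = abund_threshold,
    set_prevalence = set_prevalence,
    enrichment_prevalence = enrichment_prevalence,
    enrichment_min_mean = enrichment_min_mean,
    permutations = as.integer(permutations),
    bootstrap_iterations = as.integer(bootstrap_iterations),
    inner_permutations = as.integer(inner_permutations),
    min_group_size = as.integer(min_group_size),
    read_length = as.integer(read_length)), class = "runConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the [runConfig()] arguments
#' @return validated `runConfig`
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null", digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.writeTSV <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis chain
#'
#' Executes, in dependency order: coverage gating, alpha diversity with
#' within-farm breed comparisons, Bray-Curtis + PCoA, stratified
#' PERMANOVA (per farm: breed + age stage + batch; per age stage:
#' farm + breed + batch; sequential and marginal SS), alpha and beta
#' bootstraps, shared-taxa intersections (breeds within each farm, farms
#' within each breed), and breed / age-stage enrichment. Results are
#' written as TSV files plus a JSON manifest recording the config hash,
#' seed and per-stage counts; reruns with the same config and cohort are
#' byte-identical.
#'
#' @param config a [runConfig()]
#' @param cohort optional [CohortExperiment-class]; when NULL the cohort
#'   is read from `config$input_dir`
#' @return the manifest list, invisibly
#' @export
runAll <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "runConfig"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  manifest <- list(package = "boarMicrobiome",
                   version = as.character(utils::packageVersion("boarMicrobiome")),
                   config = unclass(config),
                   config_hash = .configHash(config),
                   seed = config$seed, stages = list())

  cohort <- .stage("load", {
    if (is.null(cohort)) {
      if (is.null(config$input_dir)) stop("no cohort and no input_dir")
      readCohort(config$input_dir, read_length = config$read_length)
    } else cohort
  })
  manifest$stages$load <- list(samples = ncol(cohort), taxa = nrow(cohort))

  gated <- .stage("coverage_gate",
                  gateByCoverage(cohort, config$coverage_threshold))
  ab <- tpm(gated)
  meta <- sampleData(gated)
  manifest$stages$coverage_gate <- list(
    detected_entries = sum(ab > 0),
    mean_richness = mean(rowSums(ab > 0)))

  alpha <- .stage("alpha_diversity", {
    a <- alphaDiversity(ab)
    .writeTSV(a, file.path(out, "alpha_diversity.tsv"))
    cmp <- do.call(rbind, lapply(unique(meta$farm), function(fm) {
      sel <- meta$farm == fm
      data.frame(farm = fm,
                 compareGroupsAlpha(a[sel, ], meta$breed[sel]))
    }))
    .writeTSV(cmp, file.path(out, "alpha_comparisons.tsv"))
    a
  })
  manifest$stages$alpha_diversity <- list(samples = nrow(alpha))

  ord <- .stage("beta_diversity", {
    d <- brayCurtis(ab)
    pc <- pcoa(d, n_axes = 2)
    coords <- data.frame(sample_id = rownames(pc$coordinates),
                         pc$coordinates)
    .writeTSV(coords, file.path(out, "pcoa_coordinates.tsv"))
    .writeTSV(data.frame(axis = seq_along(pc$eigenvalues),
                         eigenvalue = pc$eigenvalues),
              file.path(out, "pcoa_eigenvalues.tsv"))
    list(d = d, pc = pc)
  })
  manifest$stages$beta_diversity <- list(
    axes = ncol(ord$pc$coordinates),
    negative_eigenvalues = length(ord$pc$negative_eigenvalues))

  perm <- .stage("permanova", {
    res <- list()
    for (md in c("sequential", "marginal")) {
      by_farm <- permanovaByStratum(
        ab, meta, "farm", c("breed", "age_stage", "batch"),
        min_group_size = config$min_group_size,
        permutations = config$permutations, mode = md, seed = seeds[1])
      by_stage <- permanovaByStratum(
        ab, meta, "age_stage", c("breed", "farm", "batch"),
        min_group_size = config$min_group_size,
        permutations = config$permutations, mode = md, seed = seeds[2])
      res[[md]] <- list(farm = by_farm, stage = by_stage)
      flat <- do.call(rbind, lapply(
        c(stats::setNames(by_farm$results,
                          paste0("farm:", names(by_farm$results))),
          stats::setNames(by_stage$results,
                          paste0("stage:", names(by_stage$results)))),
        function(x) data.frame(term = rownames(x), as.data.frame(x))))
      flat <- data.frame(stratum = sub("\\..*$", "", rownames(flat)), flat,
                         row.names = NULL)
      .writeTSV(flat, file.path(out, sprintf("permanova_%s.tsv", md)))
    }
    res
  })
  manifest$stages$permanova <- list(
    farm_strata = length(perm$sequential$farm$results),
    stage_strata = length(perm$sequential$stage$results),
    excluded_levels = nrow(perm$sequential$farm$dropped))

  boot <- .stage("bootstrap", {
    ba <- bootstrapAlpha(ab, meta, n_iterations = config$bootstrap_iterations,
                         seed = seeds[3])
    bb <- bootstrapBeta(ab, meta,
                        n_iterations = config$bootstrap_iterations,
                        inner_permutations = config$inner_permutations,
                        seed = seeds[4])
    alpha_tab <- do.call(rbind, lapply(names(ba), function(fm)
      data.frame(farm = fm, index = colnames(ba[[fm]]$p_values),
                 stability_fraction = ba[[fm]]$stability_fraction,
                 median_p = ba[[fm]]$median_p,
                 subsample_size = ba[[fm]]$subsample_size,
                 row.names = NULL)))
    .writeTSV(alpha_tab, file.path(out, "bootstrap_alpha.tsv"))
    .writeTSV(data.frame(iteration = seq_len(nrow(bb$p_values)),
                         p = bb$p_values[, 1]),
              file.path(out, "bootstrap_beta_p.tsv"))
    list(alpha = ba, beta = bb)
  })
  manifest$stages$bootstrap <- list(
    alpha_strata = length(boot$alpha),
    beta_stability = unname(boot$beta$stability_fraction))

  shared <- .stage("shared_taxa", {
    reports <- list()
    rows <- list()
    for (fm in unique(meta$farm)) {
      fam <- buildGroupSets(ab, meta, "breed", within = c(farm = fm),
                            min_prevalence = config$set_prevalence,
                            abund_threshold = config$abund_threshold)
      reports[[paste0("farm:", fm)]] <- intersectReport(fam)
    }
    for (br in unique(meta$breed)) {
      fam <- buildGroupSets(ab, meta, "farm", within = c(breed = br),
                            min_prevalence = config$set_prevalence,
                            abund_threshold = config$abund_threshold)
      reports[[paste0("breed:", br)]] <- intersectReport(fam)
    }
    for (nm in names(reports))
      rows[[nm]] <- data.frame(scope = nm, reports[[nm]]$exclusive)
    .writeTSV(do.call(rbind, rows), file.path(out, "shared_taxa.tsv"))
    reports
  })
  manifest$stages$shared_taxa <- list(scopes = length(shared))

  enr <- .stage("enrichment", {
    res <- list()
    for (pr in c("breed", "age_stage")) {
      lvl_n <- table(droplevels(factor(meta[[pr]])))
      if (length(lvl_n) != 3L || min(lvl_n) < 3L) {
        message(sprintf("  skipping %s enrichment: level sizes %s", pr,
                        paste(names(lvl_n), lvl_n, sep = "=",
                              collapse = ", ")))
        res[[pr]] <- NULL
        next
      }
      r <- runEnrichment(ab, meta, primary = pr,
                         q_threshold = 0.05,
                         min_prev = config$enrichment_prevalence,
                         min_mean = config$enrichment_min_mean)
      .writeTSV(merge(r$models, r$labels, by = "taxon"),
                file.path(out, sprintf("enrichment_%s.tsv", pr)))
      res[[pr]] <- r
    }
    tr <- plantedTruth(cohort)
    if (!is.null(tr) && nrow(tr)) {
      ev <- evaluateEnrichment(res$breed, tr)
      writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA),
                 file.path(out, "enrichment_truth_eval.json"))
    }
    res
  })
  nlab <- function(r) if (is.null(r)) NA_integer_ else
    sum(r$labels$label != "none")
  manifest$stages$enrichment <- list(
    breed_labels = nlab(enr$breed),
    stage_labels = nlab(enr$age_stage))

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(out, "manifest.json"))
  invisible(manifest)
}
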