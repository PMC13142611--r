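# Federated pipeline orchestration: per-cohort compute, summary-statistic
# exchange, meta-analysis and downstream decompositions. Individual-level
# data never leaves a cohort directory; only association summary tables
# enter the meta stage.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full analysis pipeline on simulated or on-disk cohorts
#'
#' Executes genotype -> scale -> per-cohort association -> fixed-effects
#' meta -> dose-response decomposition -> additivity, writing a
#' federated directory layout under `out_dir`:
#' `cohorts/<id>/` (individual-level data: cohort table, calls, wide
#' genotypes), `summary/` (per-cohort association TSVs: the only files
#' the meta stage reads), `meta/` (pooled tables, dose points, component
#' fits, additivity tests) and `manifest.json` (seeds, filters, file
#' digests). Deterministic for a fixed config: rerunning writes
#' byte-identical meta tables.
#'
#' @param config A [sim_config()] describing the cohorts to generate.
#' @param out_dir Output directory (created).
#' @param traits Traits to analyze.
#' @param min_carriers_assoc Per-cohort minimum carriers for a span to be
#'   fitted (default 1).
#' @param min_carriers_meta Combined-carrier filter at meta (default 10).
#' @param bonferroni_m Correction count for main-effect significance.
#' @param keep_cohort_files Set `FALSE` to delete individual-level files
#'   once summaries are written (the federation contract: later stages
#'   must still run).
#' @return List of class `cnvdose_run`: `meta` (per trait), `dose`,
#'   `additivity`, `paths`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         traits = c("height", "bmi"),
                         min_carriers_assoc = 1,
                         min_carriers_meta = 10,
                         bonferroni_m = 47,
                         keep_cohort_files = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "summary"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "meta"), showWarnings = FALSE)
  sim <- simulate_cohorts(config)
  ef <- sim$truth$effects
  keys <- unique(ef$key)
  log <- list()
  # --- per-cohort stage: individual-level data stays in cohorts/<id> ---
  for (cid in names(sim$cohorts)) {
    cdir <- file.path(out_dir, "cohorts", cid)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    dat <- sim$cohorts[[cid]]$data
    calls <- sim$cohorts[[cid]]$calls
    .write_tsv(dat, file.path(cdir, "cohort.tsv"))
    if (!is.null(calls)) {
      .write_tsv(calls[, c("chrom", "start", "end", "sample_id", "state",
                           "quality")],
                 file.path(cdir, "calls.bed"))
      geno <- genotype_matrix(calls, config$catalog, samples = dat$sample_id)
      wide <- genotypes_wide(geno)
    } else {
      wide <- truth_genotypes_wide(sim, cid, keys)
    }
    .write_tsv(wide, file.path(cdir, "genotypes.tsv"))
    cohort <- merge(dat, wide, by = "sample_id", sort = TRUE)
    assoc_rows <- list()
    for (trait in traits) {
      scaled <- scale_adult_trait(cohort[[paste0(trait, "_raw")]],
                                  cohort$sex, cohort$age)
      cohort[[trait]] <- scaled$values
      for (k in intersect(keys, names(cohort))) {
        g <- cohort[[k]]
        if (sum(g %in% c("DEL", "DUP")) < min_carriers_assoc) next
        res <- fit_main_effect(cohort, trait, k)
        res$trait <- trait
        assoc_rows[[length(assoc_rows) + 1L]] <- res
      }
    }
    assoc <- do.call(rbind, assoc_rows)
    .write_tsv(assoc, file.path(out_dir, "summary",
                                paste0(cid, "_assoc.tsv")))
    log[[cid]] <- list(n = nrow(dat), n_calls = if (is.null(calls)) 0L else nrow(calls),
                       n_assoc_rows = nrow(assoc))
    if (!keep_cohort_files) unlink(cdir, recursive = TRUE)
  }
  # --- meta stage: reads ONLY the summary directory ---
  res <- meta_stage(file.path(out_dir, "summary"),
                    file.path(out_dir, "meta"),
                    traits = traits, min_carriers = min_carriers_meta,
                    bonferroni_m = bonferroni_m, catalog = config$catalog)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cnvdose")),
    seed = config$seed,
    filters = list(min_carriers_assoc = min_carriers_assoc,
                   min_carriers_meta = min_carriers_meta,
                   bonferroni_m = bonferroni_m),
    cohorts = log,
    file_digests = as.list(tools::md5sum(
      list.files(file.path(out_dir, "meta"), full.names = TRUE))))
  names(manifest$file_digests) <- basename(names(manifest$file_digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(c(res, list(paths = list(out_dir = out_dir),
                        manifest = manifest)),
            class = "cnvdose_run")
}

#' Meta stage: pool per-cohort association summaries
#'
#' Consumes only the summary-statistic TSVs written by the per-cohort
#' stage (individual-level files may already be gone) and writes pooled
#' meta tables, dose-response points, component fits and additivity
#' tests for any segmented locus.
#'
#' @param summary_dir Directory of `*_assoc.tsv` files.
#' @param meta_dir Output directory.
#' @param traits Traits to pool.
#' @param min_carriers Combined-carrier filter.
#' @param bonferroni_m Correction count for significance flags.
#' @param catalog Catalog (for segmented-locus additivity).
#' @return List: `meta` (named by trait), `dose`, `additivity`.
#' @export
meta_stage <- function(summary_dir, meta_dir, traits = c("height", "bmi"),
                       min_carriers = 10, bonferroni_m = 47,
                       catalog = default_catalog()) {
  files <- sort(list.files(summary_dir, pattern = "_assoc\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no association summaries in ", summary_dir)
  assoc <- do.call(rbind, lapply(files, .read_tsv))
  meta <- list()
  dose <- list()
  addv <- list()
  for (trait in traits) {
    sub <- assoc[assoc$trait == trait, , drop = FALSE]
    mt <- meta_assoc(sub, min_carriers = min_carriers)
    mt$significant <- bonferroni(mt$p, m = bonferroni_m)$significant
    meta[[trait]] <- mt
    .write_tsv(mt, file.path(meta_dir, paste0("meta_", trait, ".tsv")))
    del <- mt[mt$allele == "DEL", ]
    dup <- mt[mt$allele == "DUP", ]
    pts <- tryCatch(build_dose_points(del, dup, min_carriers = min_carriers),
                    error = function(e) NULL)
    if (!is.null(pts)) {
      .write_tsv(pts, file.path(meta_dir, paste0("dose_points_", trait, ".tsv")))
      dose[[trait]] <- pts
    }
    # additivity for composite spans of segmented loci
    for (locus in catalog) {
      multi <- Filter(function(sp) length(sp$segments) > 1L, locus$spans)
      for (sp in multi) {
        comp_keys <- span_key(locus$locus_id, sp$segments)
        full_key <- span_key(locus$locus_id, sp$name)
        for (al in c("DEL", "DUP")) {
          comp <- mt[mt$span %in% comp_keys & mt$allele == al, ]
          obs <- mt[mt$span == full_key & mt$allele == al, ]
          if (nrow(comp) == length(comp_keys) && nrow(obs) == 1L) {
            exp_ <- expected_combined(
              data.frame(span = sp$segments, beta = comp$beta[
                match(comp_keys, comp$span)],
                se = comp$se[match(comp_keys, comp$span)]), locus)
            at <- additivity_test(obs$beta, obs$se, exp_)
            at$trait <- trait
            at$span <- full_key
            at$allele <- al
            addv[[length(addv) + 1L]] <- at
          }
        }
      }
    }
  }
  addv <- if (length(addv)) do.call(rbind, addv) else NULL
  if (!is.null(addv)) {
    .write_tsv(addv, file.path(meta_dir, "additivity.tsv"))
  }
  list(meta = meta, dose = dose, additivity = addv)
}

#' @export
print.cnvdose_run <- function(x, ...) {
  cat("<cnvdose_run>", x$paths$out_dir, "\n")
  for (tr in names(x$meta)) {
    mt <- x$meta[[tr]]
    cat(sprintf("  %s: %d alleles pooled, %d Bonferroni-significant\n",
                tr, nrow(mt), sum(mt$significant)))
  }
  invisible(x)
}

#' Validate pipeline input files
#'
#' Schema, coordinate and join-key checks for a cohort phenotype TSV, a
#' CNV call BED and/or a catalog JSON. Problems are reported, never
#' silently fixed. A heuristic off-by-one detector flags catalogs that
#' look 1-based inclusive (round segment lengths only after adding 1).
#'
#' @param cohort_path,calls_path,catalog_path Optional file paths.
#' @param require_pgs Require PGS columns in the cohort table (needed for
#'   interaction models).
#' @return List of class `validation_report`: `errors`, `warnings`;
#'   `ok` is TRUE when no errors.
#' @export
validate_inputs <- function(cohort_path = NULL, calls_path = NULL,
                            catalog_path = NULL, require_pgs = FALSE) {
  errors <- character(0)
  warnings <- character(0)
  cohort <- NULL
  if (!is.null(cohort_path)) {
    cohort <- tryCatch(.read_tsv(cohort_path), error = function(e) NULL)
    if (is.null(cohort)) {
      errors <- c(errors, paste("cannot parse cohort file:", cohort_path))
    } else {
      need <- c("sample_id", "sex", "age")
      miss <- setdiff(need, names(cohort))
      if (length(miss)) {
        errors <- c(errors, paste("cohort file missing column(s):",
                                  paste(miss, collapse = ", ")))
      }
      if (require_pgs) {
        miss <- setdiff(c("PGS_height", "PGS_BMI"), names(cohort))
        if (length(miss)) {
          errors <- c(errors,
                      paste("interaction models requested but cohort file",
                            "missing column(s):", paste(miss, collapse = ", ")))
        }
      }
    }
  }
  if (!is.null(calls_path)) {
    calls <- tryCatch(.read_tsv(calls_path), error = function(e) NULL)
    if (is.null(calls)) {
      errors <- c(errors, paste("cannot parse calls file:", calls_path))
    } else {
      need <- c("chrom", "start", "end", "sample_id", "state")
      miss <- setdiff(need, names(calls))
      if (length(miss)) {
        errors <- c(errors, paste("calls file missing column(s):",
                                  paste(miss, collapse = ", ")))
      } else {
        if (any(calls$start >= calls$end)) {
          errors <- c(errors, "calls with start >= end")
        }
        if (!all(calls$state %in% c("DEL", "DUP"))) {
          errors <- c(errors, "call states outside {DEL, DUP}")
        }
        if (!is.null(cohort) &&
            !any(calls$sample_id %in% cohort$sample_id)) {
          errors <- c(errors,
                      "no call sample_id matches the cohort table (join-key mismatch)")
        }
      }
    }
  }
  if (!is.null(catalog_path)) {
    cat_ <- tryCatch(load_catalog(catalog_path),
                     error = function(e) {
                       errors <<- c(errors, paste("catalog:", conditionMessage(e)))
                       NULL
                     })
    if (!is.null(cat_)) {
      lens0 <- lens1 <- numeric(0)
      for (locus in cat_) for (s in locus$segments) {
        lens0 <- c(lens0, s$end - s$start)
        lens1 <- c(lens1, s$end - s$start + 1)
      }
      round0 <- mean(lens0 %% 1000 == 0)
      round1 <- mean(lens1 %% 1000 == 0)
      if (round1 > 0.8 && round0 < round1) {
        warnings <- c(warnings,
                      paste("segment lengths look 1-based inclusive",
                            "(round only after +1); consider one_based = TRUE"))
      }
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$ok) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
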