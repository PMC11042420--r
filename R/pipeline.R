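## pipeline_cli: orchestrate validate -> classify -> signatures -> tree ->
## chronology -> omics from a single config, with a manifest for
## reproducibility.

default_run_config <- function() {
  list(
    inputs = list(mutations = NULL, dialect = "long", fields = NULL,
                  signatures = NULL, pathways = NULL, abundance = NULL,
                  omics_groups = NULL, driver_genes = NULL),
    stages = list(classify = TRUE, signatures = TRUE, tree = TRUE,
                  chronology = TRUE, omics = FALSE),
    params = list(seed = NULL, vaf_threshold = 0.01, high_vaf = 0.20,
                  consistency = 0.90, bootstrap_B = 200L, sigma = 6,
                  nu0 = 1.0, cells = 5e3, phase_cutoff = 5.0,
                  tree_method = "auto", tree_restarts = 25L,
                  ssgsea_tau = 0.75),
    out_dir = NULL)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline run configuration
#'
#' @param x a JSON file path or a named list; missing entries take
#'   defaults.  `params$seed` and `out_dir` are mandatory (no wall-clock
#'   seeding).
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(x) {
  user <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
          else x
  cfg <- merge_config(default_run_config(), user)
  assert_that(!is.null(cfg$params$seed), "config must set params$seed")
  assert_that(!is.null(cfg$out_dir), "config must set out_dir")
  assert_that(!is.null(cfg$inputs$mutations) && !is.null(cfg$inputs$fields),
              "config must set inputs$mutations and inputs$fields")
  if (isTRUE(cfg$stages$chronology) && !isTRUE(cfg$stages$classify)) {
    stop_of("stage 'chronology' requires stage 'classify' to be enabled")
  }
  if (isTRUE(cfg$stages$signatures) && is.null(cfg$inputs$signatures)) {
    stop_of("stage 'signatures' requires inputs$signatures")
  }
  if (isTRUE(cfg$stages$omics) &&
      (is.null(cfg$inputs$abundance) || is.null(cfg$inputs$pathways))) {
    stop_of("stage 'omics' requires inputs$abundance and inputs$pathways")
  }
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the whole-organ analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every output
#' table to `out_dir`, and finishes with `manifest.json` recording input
#' hashes, the config, package version and output hashes.  Identical
#' config + inputs give identical outputs.
#'
#' @param config a config list / JSON path accepted by
#'   [load_run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  in_files <- Filter(function(x) is.character(x) && file.exists(x),
                     cfg$inputs)
  manifest <- list(
    package = "organfield",
    version = as.character(utils::packageVersion("organfield")),
    config = unclass(cfg),
    input_md5 = as.list(tools::md5sum(unlist(in_files))),
    outputs = list(), stages_run = character(0))
  outputs <- character(0)
  stage <- "validate"
  result <- tryCatch({
    mt <- read_mutation_table(cfg$inputs$mutations,
                              dialect = cfg$inputs$dialect,
                              driver_genes = cfg$inputs$driver_genes)
    map <- read_field_annotations(cfg$inputs$fields)
    assert_that(all(mt$vafs$fields %in% map$field_id),
                "mutation table contains fields absent from the organ map")
    calls <- NULL
    if (isTRUE(cfg$stages$classify)) {
      stage <- "classify"
      calls <- classify_mutations(mt$vafs, p$vaf_threshold, p$high_vaf,
                                  p$consistency)
      outputs <- c(outputs, write_tsv(calls,
                                      file.path(cfg$out_dir, "class_calls.tsv")))
      summ <- class_summary(calls, mt$records, map, mt$vafs,
                            p$vaf_threshold)
      outputs <- c(outputs,
                   write_tsv(summ$per_field,
                             file.path(cfg$out_dir, "class_per_field.tsv")))
      manifest$stages_run <- c(manifest$stages_run, "classify")
    }
    if (isTRUE(cfg$stages$signatures)) {
      stage <- "signatures"
      W <- read_signature_matrix(cfg$inputs$signatures)
      boot <- bootstrap_signature_pvalues(mt$records, W,
                                          B = p$bootstrap_B,
                                          seed = p$seed)
      wtab <- data.frame(signature = names(boot$H_obs),
                         weight = boot$H_obs, p_null = boot$p_null,
                         p_literal = boot$p_literal,
                         significant = boot$significant,
                         row.names = NULL)
      outputs <- c(outputs,
                   write_tsv(wtab, file.path(cfg$out_dir,
                                             "signature_weights.tsv")))
      manifest$stages_run <- c(manifest$stages_run, "signatures")
    }
    if (isTRUE(cfg$stages$tree)) {
      stage <- "tree"
      chars <- binarize(mt$vafs, p$vaf_threshold)
      dm <- hamming_matrix(chars)
      outputs <- c(outputs,
                   write_tsv(data.frame(sample = rownames(dm), dm,
                                        check.names = FALSE),
                             file.path(cfg$out_dir, "hamming.tsv")))
      tree <- parsimony_tree(chars, method = p$tree_method,
                             seed = p$seed, restarts = p$tree_restarts)
      outputs <- c(outputs,
                   write_tree_newick(tree, file.path(cfg$out_dir,
                                                     "tree.nwk")))
      outputs <- c(outputs,
                   write_tsv(data.frame(order = tree_sample_order(tree)),
                             file.path(cfg$out_dir, "tree_order.tsv")))
      manifest$stages_run <- c(manifest$stages_run, "tree")
    }
    if (isTRUE(cfg$stages$chronology)) {
      stage <- "chronology"
      ccfg <- chronology_config(sigma = p$sigma, nu0 = p$nu0,
                                cells = p$cells,
                                phase_cutoff_years = p$phase_cutoff,
                                vaf_threshold = p$vaf_threshold)
      fits <- fit_chronology(mt$vafs, ccfg)
      rep <- chronology_report(fits, calls, mt$records)
      outputs <- c(outputs,
                   write_tsv(rep$fits, file.path(cfg$out_dir,
                                                 "chronology_fits.tsv")),
                   write_tsv(rep$per_class,
                             file.path(cfg$out_dir,
                                       "chronology_per_class.tsv")),
                   write_tsv(rep$per_phase,
                             file.path(cfg$out_dir,
                                       "chronology_per_phase.tsv")))
      manifest$stages_run <- c(manifest$stages_run, "chronology")
    }
    if (isTRUE(cfg$stages$omics)) {
      stage <- "omics"
      m <- impute_half_min(read_abundance_matrix(cfg$inputs$abundance))
      sets <- read_gmt(cfg$inputs$pathways)
      groups <- unlist(cfg$inputs$omics_groups)[colnames(m)]
      assert_that(!anyNA(groups), "omics_groups must label every sample")
      es <- ssgsea(m, sets, weight_exponent = p$ssgsea_tau)
      outputs <- c(outputs,
                   write_tsv(data.frame(pathway = rownames(es), es,
                                        check.names = FALSE),
                             file.path(cfg$out_dir, "ssgsea.tsv")))
      manifest$stages_run <- c(manifest$stages_run, "omics")
    }
    TRUE
  }, error = function(e) e)
  if (inherits(result, "error")) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(result)
    manifest$outputs <- as.list(tools::md5sum(outputs))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    stop_of("pipeline aborted in stage '%s': %s", stage,
            conditionMessage(result))
  }
  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
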