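# Orchestration: one reproducible run of mine -> mass-match -> phylo ->
# synteny from a flat key/value config, with per-stage JSON reports and a
# provenance block. Machine outputs go to files only; a run's config and
# inputs determine its outputs bit for bit (all randomness is seeded from
# the config).

.CONFIG_DEFAULTS <- list(
  min_codons = 50, tolerance = 0.5, model = "poisson",
  gap_mode = "pairwise", n_reps = 100, k = 10, n_perm = 999, seed = 1
)

#' Read a run configuration
#'
#' Flat key/value YAML. Unset keys fall back to package defaults
#' (`min_codons` 50, `tolerance` 0.5 Da, `model` poisson, `gap_mode`
#' pairwise, `n_reps` 100, `k` 10, `n_perm` 999, `seed` 1).
#'
#' @param path YAML file path.
#' @return Named list (class `rfamide_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_config(cfg)
}

#' @rdname read_config
#' @param config named list of config values.
#' @export
as_config <- function(config) {
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, as.list(config))
  class(cfg) <- "rfamide_config"
  cfg
}

#' Validate a run configuration
#'
#' Every path, range and enumerated value is checked; all problems are
#' reported at once.
#'
#' @param config named list or `rfamide_config`.
#' @return Character vector of error messages (length zero when valid).
#' @export
validate_config <- function(config) {
  cfg <- as_config(config)
  errors <- character()
  need <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  need(!is.null(cfg$out_dir) && is.character(cfg$out_dir),
       "out_dir is required")
  for (key in c("fasta", "peaks", "peptides", "alignment",
                "table_a", "table_b", "orthology")) {
    if (!is.null(cfg[[key]])) {
      need(file.exists(cfg[[key]]),
           paste0(key, ": file not found: ", cfg[[key]]))
    }
  }
  need(is.numeric(cfg$min_codons) && cfg$min_codons >= 1,
       "min_codons must be >= 1")
  need(is.numeric(cfg$tolerance) && cfg$tolerance > 0,
       "tolerance must be > 0")
  need(cfg$model %in% c("poisson", "p"), "model must be 'poisson' or 'p'")
  need(cfg$gap_mode %in% c("pairwise", "complete"),
       "gap_mode must be 'pairwise' or 'complete'")
  need(is.numeric(cfg$n_reps) && cfg$n_reps >= 1, "n_reps must be >= 1")
  need(is.numeric(cfg$k) && cfg$k >= 0, "k must be >= 0")
  need(is.numeric(cfg$n_perm) && cfg$n_perm >= 99, "n_perm must be >= 99")
  need(is.numeric(cfg$seed), "seed must be numeric")
  synteny_keys <- c("table_a", "table_b", "orthology", "focal_a", "focal_b")
  present <- vapply(synteny_keys, function(k) !is.null(cfg[[k]]), logical(1L))
  if (any(present) && !all(present)) {
    errors <- c(errors, paste0(
      "synteny stage needs all of ", paste(synteny_keys, collapse = ", "),
      "; missing: ", paste(synteny_keys[!present], collapse = ", ")))
  }
  if (!is.null(cfg$peaks) && is.null(cfg$fasta) && is.null(cfg$peptides)) {
    errors <- c(errors,
                "peaks given but no peptide candidates (set fasta or peptides)")
  }
  errors
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

.config_md5 <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  .write_json(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the discovery workflow
#'
#' Executes, in order and skipping stages whose inputs are absent from the
#' config: precursor mining (`fasta`), mass-spectral matching (`peaks` plus
#' candidates from the mining stage or a `peptides` TSV), phylogenetics
#' (`alignment`, optional `outgroup`), and synteny (`table_a`, `table_b`,
#' `orthology`, `focal_a`, `focal_b`). Each stage writes its own files under
#' `out_dir`; a combined `report.json` carries results and a provenance
#' block (config hash, package and R versions, seed). Logging goes to
#' stderr; stage failure aborts with the stage name, retaining partial
#' outputs.
#'
#' @param config an `rfamide_config`, plain named list, or path to a YAML
#'   config file.
#' @param quiet suppress progress messages.
#' @return The run report, invisibly.
#' @export
run_discovery <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else as_config(config)
  errors <- validate_config(cfg)
  if (length(errors)) {
    stop("invalid config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[rfamide] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  report <- list(
    provenance = list(package = "rfamide",
                      package_version = as.character(
                        utils::packageVersion("rfamide")),
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = "."),
                      seed = cfg$seed,
                      config = cfg[order(names(cfg))],
                      config_md5 = .config_md5(cfg)),
    stages = list())
  candidates <- NULL

  if (!is.null(cfg$fasta)) {
    say("mine: annotating precursors from ", cfg$fasta)
    report$stages$mine <- stage("mine", {
      seqs <- read_dna_fasta(cfg$fasta)
      anns <- lapply(seq_along(seqs), function(i) {
        annotate_precursor(seqs[[i]], id = names(seqs)[i],
                           min_codons = cfg$min_codons)
      })
      tab <- peptide_table(anns)
      utils::write.table(tab, file.path(cfg$out_dir, "peptides.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out <- lapply(anns, function(a) {
        list(id = a$id,
             orf = if (is.null(a$orf)) NULL else as.list(a$orf),
             signal_end = if (is.na(a$signal_end)) NULL else a$signal_end,
             n_cleavage_sites = if (is.null(a$cleavage_sites)) 0L else
               nrow(a$cleavage_sites),
             peptides = if (is.null(a$peptides)) list() else a$peptides)
      })
      .write_json(out, file.path(cfg$out_dir, "mine.json"))
      candidates <- tab
      list(n_records = length(seqs), n_peptides = nrow(tab))
    })
  } else {
    say("mine: skipped (no fasta)")
  }

  if (!is.null(cfg$peaks)) {
    say("ms-match: matching ", cfg$peaks)
    report$stages$ms_match <- stage("ms_match", {
      peaks <- read_peak_list(cfg$peaks)
      cand <- if (!is.null(cfg$peptides)) {
        utils::read.table(cfg$peptides, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      } else {
        data.frame(sequence = candidates$peptide_seq,
                   amidated = candidates$amidated,
                   stringsAsFactors = FALSE)
      }
      if (!"sequence" %in% names(cand) && "peptide_seq" %in% names(cand)) {
        cand$sequence <- cand$peptide_seq
      }
      ranked <- identify_peptides(peaks, cand, tolerance = cfg$tolerance)
      utils::write.table(ranked, file.path(cfg$out_dir, "ms_match.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      top <- ranked[1L, ]
      out <- list(n_peaks = nrow(peaks), tolerance = cfg$tolerance,
                  top_hit = as.list(top), ranking = ranked)
      .write_json(out, file.path(cfg$out_dir, "ms_match.json"))
      out
    })
  } else {
    say("ms-match: skipped (no peaks)")
  }

  if (!is.null(cfg$alignment)) {
    say("phylo: NJ + bootstrap on ", cfg$alignment)
    report$stages$phylo <- stage("phylo", {
      aln <- read_alignment(cfg$alignment)
      tree <- bootstrap_support(aln, model = cfg$model,
                                gap_mode = cfg$gap_mode,
                                n_reps = cfg$n_reps, seed = cfg$seed)
      supports <- attr(tree, "bipartition_support")
      if (!is.null(cfg$outgroup)) {
        tree <- root_with_outgroup(tree, cfg$outgroup)
      }
      write_newick(tree, file.path(cfg$out_dir, "tree.nwk"))
      utils::write.table(supports, file.path(cfg$out_dir, "supports.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_taxa = length(aln), n_reps = cfg$n_reps,
           newick = write_newick(tree), supports = supports)
    })
  } else {
    say("phylo: skipped (no alignment)")
  }

  if (!is.null(cfg$table_a)) {
    say("synteny: comparing neighborhoods")
    report$stages$synteny <- stage("synteny", {
      ta <- read_gene_table(cfg$table_a)
      tb <- read_gene_table(cfg$table_b)
      orth <- read_orthology(cfg$orthology)
      perm <- permutation_null(ta, tb, orth, cfg$focal_a, cfg$focal_b,
                               k = cfg$k, n_perm = cfg$n_perm,
                               seed = cfg$seed)
      out <- list(focal_a = cfg$focal_a, focal_b = cfg$focal_b, k = cfg$k,
                  shared_count = perm$observed$shared_count,
                  jaccard = perm$observed$jaccard,
                  max_collinear_run = perm$observed$max_collinear_run,
                  n_perm = cfg$n_perm, p_value = perm$p_value)
      .write_json(out, file.path(cfg$out_dir, "synteny.json"))
      out
    })
  } else {
    say("synteny: skipped (no gene tables)")
  }

  .write_json(report, file.path(cfg$out_dir, "report.json"))
  say("done: ", file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
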