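# End-to-end orchestration: pan-genome -> ANI -> PHI -> recombination -> BGC.

# stage -> config keys naming input files, for pre-flight validation
.stage_inputs <- list(
  pangenome = "matrix",
  ani = "orthologs",
  phi = "alignment",
  recomb = c("recent", "ancestral", "hits"),
  bgc = c("hits", "definition", "roster"))

#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stages in dependency order (pan-genome
#' statistics, ANI, PHI, recombination post-processing, BGC screening);
#' stages absent from the configuration are skipped. All referenced input
#' files are validated before any stage runs, so a missing file aborts
#' with an error naming the stage and path and no partial outputs. Each
#' stage writes its tables into `out` and returns a report recording the
#' tool version, parameters, seed, input digests, output paths and
#' headline metrics; identical configurations give identical metrics.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list. Top-level keys: `out` (output directory), `seed`
#'   (default 1), and one block per stage: `pangenome` (`matrix`,
#'   `permutations`, `fluidity_mode`, `fluidity_pairs`), `ani`
#'   (`orthologs` directory, `min_shared`), `phi` (`alignment`, `window`,
#'   `permutations`), `recomb` (`recent`, `ancestral`, `hits`,
#'   `min_coverage`, `min_identity`), `bgc` (`hits`, `definition`,
#'   `roster`, `max_evalue`, `min_fraction`).
#' @return Named list of per-stage reports (class `run_report`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) param_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stages <- intersect(names(.stage_inputs), names(config))
  if (length(stages) == 0L) param_error("configuration names no stages")
  for (st in stages) {                      # pre-flight validation
    for (key in intersect(.stage_inputs[[st]], names(config[[st]]))) {
      paths <- unlist(config[[st]][[key]])
      missing <- paths[!file.exists(paths)]
      if (length(missing))
        param_error("stage ", st, ": input file not found: ", missing[1L])
    }
  }
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  reports <- lapply(stages, function(st) {
    runner <- switch(st, pangenome = .stage_pangenome, ani = .stage_ani,
                     phi = .stage_phi, recomb = .stage_recomb,
                     bgc = .stage_bgc)
    runner(config[[st]], out_dir, seed)
  })
  names(reports) <- stages
  jsonlite::write_json(reports, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(reports)
}

.report <- function(stage, params, seed, inputs, outputs, metrics) {
  inputs <- unlist(inputs)
  structure(list(tool = "panrecom",
                 version = as.character(utils::packageVersion("panrecom")),
                 stage = stage, parameters = params, seed = seed,
                 input_digests = as.list(tools::md5sum(
                   inputs[file.exists(inputs)])),
                 outputs = outputs, metrics = metrics),
            class = "run_report")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_pangenome <- function(cfg, out_dir, seed) {
  pm <- read_presence_matrix(cfg$matrix)
  n_perm <- as.integer(cfg$permutations %||% 100L)
  summ <- summarize_pangenome(pm)
  curves <- accumulation_curves(pm, n_perm, seed = seed)
  heaps <- fit_heaps(curves)
  mode <- cfg$fluidity_mode %||% "all_pairs"
  flu <- genomic_fluidity(pm, mode = mode,
                          n_pairs = as.integer(cfg$fluidity_pairs %||% 1000L),
                          seed = seed)
  paths <- c(
    .write_tsv(data.frame(category = c("core", "soft_core", "shell",
                                       "cloud", "pan", "singletons"),
                          families = c(summ$n_core, summ$n_soft_core,
                                       summ$n_shell, summ$n_cloud,
                                       summ$n_pan, summ$n_singletons)),
               file.path(out_dir, "pangenome_summary.tsv")),
    .write_tsv(data.frame(permutation = rep(seq_len(n_perm),
                                            ncol(curves$pan_sizes)),
                          g = rep(seq_len(ncol(curves$pan_sizes)),
                                  each = n_perm),
                          pan = as.vector(curves$pan_sizes),
                          core = as.vector(curves$core_sizes),
                          new = as.vector(curves$new_genes),
                          unique = as.vector(curves$unique_genes)),
               file.path(out_dir, "accumulation_curves.tsv")))
  .report("pangenome",
          list(permutations = n_perm, fluidity_mode = mode),
          seed, cfg$matrix, paths,
          list(n_pan = summ$n_pan, n_core = summ$n_core,
               pct_core = summ$pct_core, alpha = heaps$alpha,
               verdict = heaps$verdict, phi_fluidity = flu$phi))
}

.stage_ani <- function(cfg, out_dir, seed) {
  orth <- read_ortholog_dir(cfg$orthologs)
  am <- ani_matrix(orth, min_shared = as.integer(cfg$min_shared %||% 1L))
  pairs <- ani_pairs(am)
  paths <- c(.write_tsv(cbind(genome = rownames(am$values),
                              as.data.frame(am$values)),
                        file.path(out_dir, "ani_matrix.tsv")),
             .write_tsv(pairs, file.path(out_dir, "ani_pairs.tsv")))
  .report("ani", list(min_shared = cfg$min_shared %||% 1L), seed,
          list.files(cfg$orthologs, full.names = TRUE), paths,
          list(min_ani = min(pairs$ani, na.rm = TRUE),
               n_below_cutoff = sum(!pairs$same_species)))
}

.stage_phi <- function(cfg, out_dir, seed) {
  paths_in <- unlist(cfg$alignment)
  aln <- if (length(paths_in) > 1L) concat_alignments(paths_in, "gap_fill")
         else read_fasta_alignment(paths_in)
  res <- phi_test(aln, w = as.integer(cfg$window %||% 100L),
                  n_permutations = as.integer(cfg$permutations %||% 1000L),
                  seed = seed)
  .report("phi", list(window = res$window_w,
                      permutations = res$n_permutations),
          seed, paths_in, character(0),
          list(phi_observed = res$phi_observed, p_value = res$p_value,
               n_informative = res$n_informative))
}

.stage_recomb <- function(cfg, out_dir, seed) {
  events <- read_event_table(cfg$recent, "recent")
  if (!is.null(cfg$ancestral))
    events <- rbind(events, read_event_table(cfg$ancestral, "ancestral"))
  hits <- read_blast_tab(cfg$hits)
  recent <- events[events$kind == "recent", , drop = FALSE]
  assn <- assign_donors(recent, hits,
                        min_coverage = cfg$min_coverage %||% 0.5,
                        min_identity = cfg$min_identity %||% 99)
  net <- build_network(assn)
  hw <- detect_highways(net)
  edges <- net$edges
  edges$highway <- paste(edges$donor, edges$recipient) %in%
    paste(hw$donor, hw$recipient)
  stats <- size_statistics(events)
  paths <- c(
    .write_tsv(data.frame(event_id = recent$event_id,
                          status = vapply(assn, `[[`, "", "status"),
                          donor = vapply(assn, `[[`, "", "donor_genome")),
               file.path(out_dir, "donor_assignments.tsv")),
    .write_tsv(edges, file.path(out_dir, "recomb_edges.tsv")),
    .write_tsv(gene_recombination_counts(events),
               file.path(out_dir, "gene_recomb_counts.tsv")))
  jsonlite::write_json(unclass(stats), file.path(out_dir, "size_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  .report("recomb", list(min_coverage = cfg$min_coverage %||% 0.5,
                         min_identity = cfg$min_identity %||% 99),
          seed, c(cfg$recent, cfg$ancestral, cfg$hits),
          c(paths, file.path(out_dir, "size_stats.json")),
          list(n_events = nrow(events), n_assigned = net$n_assigned,
               n_highways = nrow(hw),
               median_fragment = stats$median_length))
}

.stage_bgc <- function(cfg, out_dir, seed) {
  hits <- read_blast_tab(cfg$hits)
  bgc <- read_bgc_definition(cfg$definition)
  roster <- if (!is.null(cfg$roster)) readLines(cfg$roster) else NULL
  calls <- call_bgc_presence(hits, bgc,
                             max_evalue = cfg$max_evalue %||% 1e-10,
                             min_fraction = cfg$min_fraction %||% 0.9,
                             roster = roster)
  path <- .write_tsv(calls, file.path(out_dir, "bgc_calls.tsv"))
  .report("bgc", list(max_evalue = cfg$max_evalue %||% 1e-10,
                      min_fraction = cfg$min_fraction %||% 0.9),
          seed, c(cfg$hits, cfg$definition, cfg$roster), path,
          list(bgc = bgc$name, n_present = sum(calls$present),
               n_genomes = nrow(calls)))
}
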