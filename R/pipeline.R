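# End-to-end orchestration: selection -> site summaries -> physchem ->
# synteny -> expression -> motifs, on user inputs or the packaged
# synthetic scenarios, with a machine-readable run manifest.

#' Validate a pipeline configuration
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `out_dir`; `seed`; optional `stages` (character subset of
#'   `c("selection", "sites", "physchem", "synteny", "expression",
#'   "motifs")`); `thresholds` (`site_p`, `er`, `min_variance`);
#'   and per-stage inputs: either `inputs` (paths: `alignment`, `tree`,
#'   `neighborhoods`, `counts`, `lengths`, `paralog_map`, `proteins`) or
#'   `simulate` (sizes for the built-in synthetic scenarios:
#'   `n_taxa`, `n_codons`).
#' @return The normalized config (invisibly errors with a report listing
#'   every failure otherwise).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character(0)
  if (is.null(config$out_dir)) problems <- c(problems, "missing out_dir")
  if (is.null(config$seed)) problems <- c(problems, "missing seed")
  all_stages <- c("selection", "sites", "physchem", "synteny",
                  "expression", "motifs")
  if (is.null(config$stages)) config$stages <- all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad)) problems <- c(problems,
                                 paste("unknown stage:", paste(bad, collapse = ", ")))
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) problems <- c(problems, paste("missing input file:", p))
  }
  th <- config$thresholds
  config$thresholds <- list(
    site_p = if (!is.null(th$site_p)) th$site_p else 0.05,
    er = if (!is.null(th$er)) th$er else 2,
    min_variance = if (!is.null(th$min_variance)) th$min_variance else 0.8)
  if (is.null(config$simulate)) config$simulate <- list()
  sim <- config$simulate
  config$simulate <- list(
    n_taxa = if (!is.null(sim$n_taxa)) sim$n_taxa else 8L,
    n_codons = if (!is.null(sim$n_codons)) sim$n_codons else 120L)
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  config
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes per-stage TSV/CSV/
#' JSON artifacts plus a manifest recording the package version, seeds,
#' thresholds, input hashes, and artifact hashes.  With the same config
#' (and seed) the deterministic stages reproduce identical artifacts.
#'
#' @param config See [validate_pipeline_config()].
#' @return The manifest (invisibly); also written as `manifest.json` in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  th <- config$thresholds
  artifacts <- list()
  timings <- list()
  note <- function(stage, file) artifacts[[stage]] <<- c(artifacts[[stage]], file)

  inputs <- config$inputs
  have <- function(x) !is.null(inputs[[x]])

  # --- inputs: load or simulate -------------------------------------------
  if (have("alignment") && have("tree")) {
    aln <- read_codon_fasta(inputs$alignment, allow_stops = TRUE)
    tree <- read_newick(path = inputs$tree)
    truth <- NULL
  } else {
    tree <- sim_tree(config$simulate$n_taxa, seed = seed)
    tree <- flag_foreground_clade(tree, tree$tip.label[1],
                                  include_clade = FALSE)
    sc <- sim_scenario(tree, kappa = 2,
                       omega = list(type = "branch_site",
                                    omega_background = 0.2, omega_plus = 4,
                                    branch_fraction = 0.3),
                       n_codons = config$simulate$n_codons, seed = seed)
    sim <- simulate_codon_alignment(sc)
    aln <- sim$alignment
    truth <- sim$truth
  }

  m0 <- NULL
  if ("selection" %in% config$stages) {
    t0 <- Sys.time()
    bt <- branch_model_test(aln, tree, optimize_branch_lengths = FALSE,
                            n_starts = 1, seed = seed)
    f <- file.path(out_dir, "branch_models.tsv")
    write_fit_report(bt, f); note("selection", f)
    m0 <- bt$m0
    timings$selection <- as.numeric(Sys.time() - t0, units = "secs")
  }
  if (is.null(m0))
    m0 <- codon_fit(aln, tree, model = "M0",
                    optimize_branch_lengths = FALSE, n_starts = 1,
                    seed = seed)

  summary_sites <- integer(0)
  if ("sites" %in% config$stages) {
    t0 <- Sys.time()
    fel <- fel_scan(aln, global_fit = m0, p_threshold = th$site_p)
    meme <- meme_scan(aln, global_fit = m0, p_threshold = th$site_p)
    bus <- busted_gene_test(aln, global_fit = m0, seed = seed)
    slac <- slac_site_counts(aln, global_fit = m0)
    summ <- summarize_selected_sites(meme, fel, bus$evidence_ratios,
                                     p_threshold = th$site_p,
                                     er_threshold = th$er)
    summary_sites <- sort(unique(c(summ$meme_sites, summ$fel_sites)))
    for (obj in list(list(fel, "fel_sites.tsv"), list(meme, "meme_sites.tsv"),
                     list(slac, "slac_counts.tsv"))) {
      f <- file.path(out_dir, obj[[2]])
      write_site_report(obj[[1]], f); note("sites", f)
    }
    f <- file.path(out_dir, "gene_summary.json")
    jsonlite::write_json(list(
      busted = list(statistic = bus$statistic, p_value = bus$p_value,
                    omega = bus$omega, weights = bus$weights),
      meme_sites = summ$meme_sites, fel_sites = summ$fel_sites,
      both = summ$both, er_supported = summ$meme_er_supported,
      thresholds = th), f, auto_unbox = TRUE, digits = NA)
    note("sites", f)
    timings$sites <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("physchem" %in% config$stages) {
    t0 <- Sys.time()
    sites <- if (length(summary_sites)) summary_sites else
      seq_len(min(10, aln$n_codons))
    zm <- encode_zmatrix(aln, sites)
    groups <- if (!is.null(config$groups)) config$groups else {
      ks <- select_k(zm, k_max = min(5, nrow(zm) - 1L), seed = seed,
                     min_variance = th$min_variance)
      ks$cluster
    }
    f <- file.path(out_dir, "zmatrix.csv")
    utils::write.csv(as.data.frame(unclass(zm)), f); note("physchem", f)
    if (length(unique(groups)) >= 2) {
      dp <- dapc(zm, groups, min_variance = th$min_variance)
      f <- file.path(out_dir, "dapc_scores.csv")
      utils::write.csv(data.frame(taxon = rownames(zm), group = groups,
                                  dp$scores, accuracy = dp$accuracy), f)
      note("physchem", f)
    }
    timings$physchem <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("synteny" %in% config$stages) {
    t0 <- Sys.time()
    nbs <- if (have("neighborhoods")) read_neighborhoods(inputs$neighborhoods)
      else {
        sim <- simulate_neighborhoods(neighborhood_scenario(
          loss_prob = c(0.15, 0.45), seed = seed))
        list(ancestor = sim$ancestor, copy1 = sim$copy1, copy2 = sim$copy2,
             reference = sim$reference)
      }
    keys <- names(nbs)
    rows <- list()
    for (i in seq_along(nbs)) for (j in seq_along(nbs)) {
      if (i >= j) next
      rows[[length(rows) + 1L]] <- data.frame(
        n1 = keys[i], n2 = keys[j],
        shared = shared_flank_count(nbs[[i]], nbs[[j]]),
        run_up = as.integer(conserved_run(nbs[[i]], nbs[[j]], "up")),
        run_down = as.integer(conserved_run(nbs[[i]], nbs[[j]], "down")))
    }
    f <- file.path(out_dir, "synteny_scores.tsv")
    utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("synteny", f)
    timings$synteny <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("expression" %in% config$stages) {
    t0 <- Sys.time()
    if (have("counts") && have("lengths") && have("paralog_map")) {
      counts <- utils::read.delim(inputs$counts)
      lens <- utils::read.delim(inputs$lengths)
      pmap <- utils::read.delim(inputs$paralog_map)
    } else {
      mm <- matrix(c(80, 60, 40, 20,
                     10, 120, 15, 30), nrow = 2, byrow = TRUE,
                   dimnames = list(c("HIF1Aa", "HIF2Aa"),
                                   c("brain", "gill", "heart", "liver")))
      sim <- simulate_expression(expression_scenario(
        species = c("sp1", "sp2", "sp3"), mean_matrix = mm, seed = seed))
      counts <- sim$counts; lens <- sim$lengths; pmap <- sim$paralog_map
    }
    tpms <- lapply(split(counts, counts$species), function(d)
      tpm_table(d, lens))
    hm <- median_heatmap(tpms, pmap)
    f <- file.path(out_dir, "median_tpm_heatmap.csv")
    write_heatmap_csv(hm, f); note("expression", f)
    timings$expression <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("motifs" %in% config$stages) {
    t0 <- Sys.time()
    prot <- translate_alignment(aln)
    hits <- list()
    for (tx in rownames(prot)) {
      s <- paste(prot[tx, prot[tx, ] != "-"], collapse = "")
      hits[[tx]] <- rbind(
        scan_lxxlap(s, id = tx)[, c("id", "start", "match", "motif")],
        scan_cterm_asn_motif(s, id = tx)[, c("id", "start", "match", "motif")])
    }
    f <- file.path(out_dir, "motif_hits.tsv")
    utils::write.table(do.call(rbind, hits), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("motifs", f)
    timings$motifs <- as.numeric(Sys.time() - t0, units = "secs")
  }

  manifest <- list(
    package = "ohnosel",
    version = as.character(utils::packageVersion("ohnosel")),
    seed = seed, thresholds = th, stages = config$stages,
    input_md5 = if (length(unlist(inputs)))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    artifacts = lapply(artifacts, function(fs)
      as.list(tools::md5sum(fs))),
    timings_sec = timings,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
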