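# End-to-end orchestration over the synthetic generators: one seed drives
# every stage, all thresholds live in the config and are echoed into the
# run manifest, and rerunning a config reproduces every output.

#' Assemble a pipeline run configuration
#'
#' All thresholds of the analysis in one validated list; the defaults are
#' the published ones (promoter window 2.5 kb, lncRNA length > 200 nt,
#' ORF < 300 nt, fold change > 2 / < 0.5 with p < 0.005 and FDR < 0.05,
#' network Z > 5, module size >= 51, strict pairing r > 0.9999).
#'
#' @param seed Master seed; every stage derives its substream from it.
#' @param window_bp,lnc_min_len,orf_max,fc_up,fc_down,p_threshold,fdr_threshold,z_threshold,module_min_size,strict_r
#'   Analysis thresholds.
#' @param n_chrom,chrom_len,n_genes,n_prompts,n_decoy_lnc,n_decoy_coding,n_reps,coupling_r,dispersion,n_de_up,n_de_down,de_lfc
#'   Synthetic-data scenario parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       window_bp = 2500, lnc_min_len = 200, orf_max = 300,
                       fc_up = 2, fc_down = 0.5, p_threshold = 0.005,
                       fdr_threshold = 0.05, z_threshold = 5,
                       module_min_size = 51, strict_r = 0.9999,
                       n_chrom = 4, chrom_len = 1e5, n_genes = 80,
                       n_prompts = 25, n_decoy_lnc = 15, n_decoy_coding = 8,
                       n_reps = 3, coupling_r = 0.65, dispersion = 0.1,
                       n_de_up = 6, n_de_down = 6, de_lfc = 3) {
  cfg <- as.list(environment())
  numeric_fields <- setdiff(names(cfg), character(0))
  for (f in numeric_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      abort(sprintf("config field '%s' must be a single non-negative number", f))
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Stages: `simulate` (genome, PROMPT loci, counts, population, divergence
#' pairs), `identify` (lncRNA filter + PROMPT classification), `de`
#' (NB differential expression), `correlate` (PROMPT-gene correlation),
#' `network` (co-expression modules), `structure` (folding + motif scan of
#' the identified lncRNAs), `popgen` (haplotypes, LD, substitution
#' ratios). Outputs are written as TSV under `out_dir` together with a
#' JSON manifest (config echo, package version, per-file MD5); reruns with
#' the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (dependencies of a requested
#'   stage are run too, but only requested stages write outputs).
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = c("simulate", "identify", "de", "correlate",
                                    "network", "structure", "popgen")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "identify", "de", "correlate", "network",
                  "structure", "popgen")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }
  seed_for <- function(key) derive_seed(config$seed, key)

  # --- simulate (always computed: later stages consume it) ----------------
  ann0 <- generate_genome(
    n_chrom = config$n_chrom, chrom_len = config$chrom_len,
    n_genes = config$n_genes, seed = seed_for("genome")
  )
  loci <- plant_prompt_loci(
    ann0, n_prompts = config$n_prompts, n_decoy_lnc = config$n_decoy_lnc,
    n_decoy_coding = config$n_decoy_coding, seed = seed_for("loci")
  )
  prompt_truth <- loci$truth %>% filter(.data$class == "prompt")
  de_ids <- with_seed(seed_for("de_pick"), {
    picks <- sample(prompt_truth$tu_id,
                    min(nrow(prompt_truth), config$n_de_up + config$n_de_down))
    list(up = head(picks, config$n_de_up),
         down = utils::tail(picks, -config$n_de_up))
  })
  lfc <- c(setNames(rep(config$de_lfc, length(de_ids$up)), de_ids$up),
           setNames(rep(-config$de_lfc, length(de_ids$down)), de_ids$down))
  pair_tbl <- tibble(prompt = prompt_truth$tu_id, gene = prompt_truth$gene_id)
  all_ids <- c(loci$tus$tu_id, loci$annotation$genes$gene_id)
  sim <- simulate_counts(
    all_ids, n_reps = config$n_reps, planted_lfc = lfc,
    dispersion = config$dispersion, pairs = pair_tbl,
    coupling_r = config$coupling_r, seed = seed_for("counts")
  )
  pop <- simulate_population(seed = seed_for("population"))
  div <- simulate_divergence(n_pairs = 100, seed = seed_for("divergence"))

  if ("simulate" %in% stages) {
    write_fasta(loci$annotation$genome, file.path(out_dir, "genome.fa"))
    outputs <- c(outputs, file.path(out_dir, "genome.fa"))
    write_gff3(loci$annotation, loci$tus, file.path(out_dir, "annotation.gff3"))
    outputs <- c(outputs, file.path(out_dir, "annotation.gff3"))
    emit(sim$counts, "counts.tsv")
    emit(loci$truth, "truth_loci.tsv")
    write_genotypes(pop$genotypes, file.path(out_dir, "haplotypes.tsv"))
    outputs <- c(outputs, file.path(out_dir, "haplotypes.tsv"))
  }

  lnc <- filter_lncrna(loci$tus)
  kept <- loci$tus %>%
    inner_join(lnc %>% filter(.data$class != "rejected") %>%
                 select("tu_id"), by = "tu_id")
  prompts <- classify_prompts(kept, loci$annotation,
                              window_bp = config$window_bp)
  if ("identify" %in% stages) {
    emit(lnc %>% select(-"sequence"), "lncrna_records.tsv")
    emit(prompts, "prompts.tsv")
    dens <- chromosome_density(
      kept %>% inner_join(prompts, by = "tu_id"), loci$annotation
    )
    emit(dens$per_chrom, "prompt_density.tsv")
  }

  lengths_all <- tibble(
    tu_id = all_ids,
    length = c(loci$tus$length,
               loci$annotation$genes$end - loci$annotation$genes$start + 1)
  )
  fpkm <- compute_fpkm(sim$counts, lengths_all)
  if ("de" %in% stages) {
    de <- nb_diff_test(sim$counts, sim$samples)
    emit(as_tibble(de), "de_results.tsv")
  }
  if ("correlate" %in% stages) {
    corr <- prompt_gene_correlation(fpkm, pair_tbl %>%
                                      rename(tu_id = "prompt", gene_id = "gene"))
    emit(corr$pairs, "pair_correlations.tsv")
    emit(corr$pooled, "pooled_correlation.tsv")
  }
  if ("network" %in% stages) {
    coex <- simulate_coexpression(seed = seed_for("coexpression"))
    net <- build_network(coex$expr, coex$kinds,
                         z_threshold = config$z_threshold)
    mods <- extract_modules(net, min_size = config$module_min_size)
    emit(net$edges, "network_edges.tsv")
    emit(mods %>% mutate(members = purrr::map_chr(.data$members, paste,
                                                  collapse = ",")),
         "network_modules.tsv")
  }
  if ("structure" %in% stages) {
    motifs <- read_motif_table()
    scaffold <- plant_structured_sequence(
      loop_motifs = c("4" = "WAACCA"), seed = seed_for("scaffold")
    )
    folded <- fold_mfe(c(scaffold = scaffold$sequence))
    ann_el <- annotate_elements(folded$dot_bracket)
    hits <- scan_motifs(c(scaffold = scaffold$sequence), motifs)
    emit(folded %>% select(-"sequence"), "structure_mfe.tsv")
    emit(hit_element_context(hits, ann_el$labels), "motif_hits.tsv")
  }
  if ("popgen" %in% stages) {
    emit(haplotype_frequencies(pop$genotypes), "haplotype_frequencies.tsv")
    emit(ld_matrix(pop$genotypes), "ld_pairs.tsv")
    ratio <- substitution_ratio(div$pairs)
    emit(ratio$summary, "substitution_ratio.tsv")
  }

  manifest <- list(
    package = "promptscape",
    version = as.character(utils::packageVersion("promptscape")),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    files = lapply(sort(outputs), function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
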