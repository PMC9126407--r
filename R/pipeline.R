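#' Configure an end-to-end analysis run
#'
#' Gathers the simulation settings and every analysis threshold in one
#' object. Defaults are the standard choices of the analysis chain: +/-500 kb
#' cis windows, hierarchical FDR at 0.05, LD pruning at r-squared 0.1,
#' co-localization decisions at posterior probability 0.75, instrument
#' threshold p < 5e-8 and the strict 75% discordance rule.
#'
#' @param sim A [sim_config()].
#' @param alpha Family-level FDR target / significance level.
#' @param r2_max LD-pruning cap.
#' @param pp_threshold Co-localization posterior threshold.
#' @param instrument_p MR instrument p-value threshold.
#' @param eqtl_p_sig Per-tissue eQTL significance flag for direction counting.
#' @param discordance_threshold Fraction of discordant tissues that must be
#'   strictly exceeded.
#' @param coloc_priors A [coloc_priors()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            alpha = 0.05,
                            r2_max = 0.1,
                            pp_threshold = 0.75,
                            instrument_p = 5e-8,
                            eqtl_p_sig = 0.05,
                            discordance_threshold = 0.75,
                            coloc_priors = omicschain::coloc_priors()) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, alpha = alpha, r2_max = r2_max,
                 pp_threshold = pp_threshold, instrument_p = instrument_p,
                 eqtl_p_sig = eqtl_p_sig,
                 discordance_threshold = discordance_threshold,
                 coloc_priors = coloc_priors),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] and whose `sim` block mirrors [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$maf_range)) sim_args$maf_range <- unlist(sim_args$maf_range)
  if (!is.null(sim_args$age_range)) sim_args$age_range <- unlist(sim_args$age_range)
  sim <- do.call(sim_config, sim_args)
  args <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the full analysis chain on a simulated study
#'
#' Executes, in order: study simulation; per-region protein (pQTL) scans with
#' age/sex adjustment; hierarchical FDR across regions; lead-pQTL extraction
#' and per-region priority LD pruning; per-tissue expression (eQTL) scans of
#' the selected regions; protein-expression co-localization per region and
#' tissue; direction-concordance classification of lead pQTLs against tissue
#' eQTLs; summary-statistics predicted-expression association (with
#' hierarchical FDR over genes and tissues); two-sample expression-on-protein
#' MR on disjoint sample halves; protein-on-disease MR with Bonferroni
#' correction; the three-way overlap of negative-evidence gene sets; and
#' mediation chains for genes in the central overlap.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV and the report as JSON-like YAML.
#' @return A `run_report` list: the gene sets, stage tables, per-stage row
#'   counts, config hash, seed and package version. Re-running with an
#'   identical configuration reproduces the identical report.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim_config(n_samples = 600, n_regions = 2,
#'                                   sign_pattern = "discordant",
#'                                   ge_pe_coupling = -0.5, seed = 11))
#' rep <- run_pipeline(cfg)
#' rep$sets$center
#' }
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  study <- simulate_study(sim)
  truth <- study$truth
  covars <- study$omics$covariates
  tissues <- names(study$omics$ge)
  genes <- truth$gene_id
  regions <- truth$region

  # --- stage 1: protein cis scans -----------------------------------------
  pe_stats <- purrr::map_dfr(seq_along(regions), function(k) {
    g <- subset_region(study$geno, regions[k])
    st <- scan_region(g, study$omics$pe[, k], covariates = covars)
    st$gene_id <- genes[k]
    st
  })

  # --- stage 2: hierarchical FDR + lead pQTLs + pruning -------------------
  hfdr <- hierarchical_fdr(pe_stats, alpha1 = config$alpha)
  sig <- significant_variants(hfdr)
  sel_regions <- unique(sig$region)
  leads <- purrr::map_dfr(sel_regions, function(r) {
    lead_variant(dplyr::filter(sig, .data$region == r))
  })
  pruned <- purrr::map_dfr(sel_regions, function(r) {
    priority_prune(dplyr::filter(sig, .data$region == r),
                   subset_region(study$geno, r), r2_max = config$r2_max)
  })

  # --- stage 3: expression scans of selected regions ----------------------
  ge_stats <- purrr::map_dfr(sel_regions, function(r) {
    k <- match(r, regions)
    g <- subset_region(study$geno, r)
    purrr::map_dfr(tissues, function(tt) {
      st <- scan_region(g, study$omics$ge[[tt]][, k], covariates = covars)
      st$gene_id <- genes[k]
      st$tissue <- tt
      st
    })
  })

  # --- stage 4: co-localization per selected region x tissue --------------
  coloc_tbl <- purrr::map_dfr(sel_regions, function(r) {
    purrr::map_dfr(tissues, function(tt) {
      res <- colocalize(dplyr::filter(pe_stats, .data$region == r),
                        dplyr::filter(ge_stats, .data$region == r,
                                      .data$tissue == tt),
                        priors = config$coloc_priors,
                        pp_threshold = config$pp_threshold)
      tibble::tibble(region = r, gene_id = genes[match(r, regions)],
                     tissue = tt, pp0 = res$pp[["pp0"]], pp1 = res$pp[["pp1"]],
                     pp2 = res$pp[["pp2"]], pp3 = res$pp[["pp3"]],
                     pp4 = res$pp[["pp4"]], n_variants = res$n_variants,
                     verdict = res$verdict)
    })
  })

  # --- stage 5: direction concordance of lead pQTLs -----------------------
  direction_tbl <- purrr::map_dfr(seq_len(nrow(leads)), function(i) {
    lead <- leads[i, ]
    eq <- ge_stats |>
      dplyr::filter(.data$region == lead$region,
                    .data$variant_id == lead$variant_id) |>
      dplyr::select("tissue", "beta", "p")
    if (nrow(eq) == 0L || all(eq$p > config$eqtl_p_sig)) {
      return(tibble::tibble(gene_id = lead$gene_id,
                            n_tissues_significant = 0L, n_discordant = 0L,
                            fraction_discordant = NA_real_,
                            verdict = "no_eqtl"))
    }
    cls <- direction_classify(lead$beta, eq, p_sig = config$eqtl_p_sig,
                              threshold = config$discordance_threshold)
    dplyr::bind_cols(tibble::tibble(gene_id = lead$gene_id), cls)
  })

  # --- stage 6: predicted-expression association (summary level) ----------
  weights <- true_weight_models(truth, tissues = tissues, geno = study$geno)
  twas_tbl <- purrr::map_dfr(sel_regions, function(r) {
    gid <- genes[match(r, regions)]
    purrr::map_dfr(tissues, function(tt) {
      w <- dplyr::filter(weights, .data$gene_id == gid, .data$tissue == tt)
      if (nrow(w) == 0L) return(NULL)
      summary_twas(dplyr::filter(pe_stats, .data$region == r), w,
                   subset_region(study$geno, r))
    })
  })
  mx_negative <- if (nrow(twas_tbl)) {
    twas_sig <- significant_variants(
      hierarchical_fdr_tissues(twas_tbl, alpha1 = config$alpha))
    unique(twas_sig$gene_id[twas_sig$effect < 0])
  } else character(0)

  # --- stage 7: two-sample MR, expression -> protein ----------------------
  half <- floor(sim$n_samples / 2)
  split <- make_two_sample_split(sim$n_samples, half, sim$n_samples - half)
  subset_samples <- function(geno, idx) {
    genotype_matrix(geno$dosages[idx, , drop = FALSE], geno$variants)
  }
  mr_ge_pe <- purrr::map_dfr(sel_regions, function(r) {
    k <- match(r, regions)
    g_exp <- subset_samples(subset_region(study$geno, r), split$exposure)
    g_out <- subset_samples(subset_region(study$geno, r), split$outcome)
    out_stats <- scan_region(g_out, study$omics$pe[split$outcome, k],
                             covariates = covars[split$outcome, ])
    purrr::map_dfr(tissues, function(tt) {
      exp_stats <- scan_region(g_exp,
                               study$omics$ge[[tt]][split$exposure, k],
                               covariates = covars[split$exposure, ])
      inst <- select_instrument(exp_stats, p_max = config$instrument_p)
      if (nrow(inst) == 0L) return(NULL)
      tibble::tibble(gene_id = genes[k], tissue = tt,
                     variant_id = inst$variant_id,
                     beta_x = inst$beta, se_x = inst$se,
                     out_stats = list(out_stats))
    })
  })
  mr_ge_pe_res <- if (nrow(mr_ge_pe)) {
    purrr::map_dfr(seq_len(nrow(mr_ge_pe)), function(i) {
      row <- mr_ge_pe[i, ]
      hit <- row$out_stats[[1]][row$out_stats[[1]]$variant_id ==
                                  row$variant_id, ]
      if (nrow(hit) == 0L) return(NULL)
      dplyr::bind_cols(dplyr::select(row, -"out_stats"),
                       beta_y = hit$beta, se_y = hit$se,
                       mr_ratio(row$beta_x, row$se_x, hit$beta, hit$se))
    })
  } else tibble::tibble()
  mr_negative <- if (nrow(mr_ge_pe_res)) {
    mr_ge_pe_res <- hierarchical_fdr_tissues(mr_ge_pe_res,
                                             alpha1 = config$alpha)$variants
    unique(mr_ge_pe_res$gene_id[mr_ge_pe_res$significant &
                                  mr_ge_pe_res$beta_iv < 0])
  } else character(0)

  # --- stage 8: protein -> disease MR (Bonferroni) ------------------------
  cad_stats <- if (nrow(leads)) {
    binary_assoc(subset_samples(study$geno, split$outcome),
                 study$outcome[split$outcome],
                 variant_ids = leads$variant_id,
                 covariates = covars[split$outcome, ])
  } else tibble::tibble()
  pe_exp <- purrr::map_dfr(seq_len(nrow(leads)), function(i) {
    lead <- leads[i, ]
    g_exp <- subset_samples(subset_region(study$geno, lead$region),
                            split$exposure)
    st <- scan_region(g_exp,
                      study$omics$pe[split$exposure, match(lead$region, regions)],
                      covariates = covars[split$exposure, ])
    inst <- select_instrument(st, p_max = config$instrument_p)
    if (nrow(inst) == 0L) return(NULL)
    tibble::tibble(exposure_id = lead$gene_id, variant_id = inst$variant_id,
                   beta_x = inst$beta, se_x = inst$se)
  })
  # outcome stats must cover the exposure-side instruments
  pe_cad <- if (nrow(pe_exp)) {
    extra <- setdiff(pe_exp$variant_id, cad_stats$variant_id)
    if (length(extra)) {
      cad_stats <- dplyr::bind_rows(
        cad_stats,
        binary_assoc(subset_samples(study$geno, split$outcome),
                     study$outcome[split$outcome], variant_ids = extra,
                     covariates = covars[split$outcome, ]))
    }
    mr_battery(pe_exp, cad_stats, correction = "bonferroni",
               alpha = config$alpha)
  } else tibble::tibble()

  # --- stage 9: overlap + mediation chains --------------------------------
  qtl_discordant <- if (nrow(direction_tbl)) {
    direction_tbl$gene_id[direction_tbl$verdict == "predominantly_discordant"]
  } else character(0)
  overlap <- overlap_sets(mx_negative, mr_negative, qtl_discordant)
  center <- attr(overlap, "center")

  chains <- purrr::map_dfr(center, function(gid) {
    legs1 <- dplyr::filter(mr_ge_pe_res, .data$gene_id == gid,
                           .data$significant)
    leg2 <- dplyr::filter(pe_cad, .data$exposure_id == gid)
    if (nrow(legs1) == 0L || nrow(leg2) == 0L) return(NULL)
    k <- match(gid, genes)
    purrr::map_dfr(seq_len(nrow(legs1)), function(i) {
      l1 <- legs1[i, ]
      # total leg: expression instrument against the disease outcome
      tot_y <- binary_assoc(subset_samples(study$geno, split$outcome),
                            study$outcome[split$outcome],
                            variant_ids = l1$variant_id,
                            covariates = covars[split$outcome, ])
      total <- mr_ratio(l1$beta_x, l1$se_x, tot_y$beta, tot_y$se)
      mediation_chain(l1, leg2[1, ], total, gene_id = gid,
                      tissue = l1$tissue, alpha = config$alpha)
    })
  })

  report <- structure(list(
    config = config,
    config_hash = rlang::hash(config),
    seed = sim$seed,
    version = as.character(utils::packageVersion("omicschain")),
    counts = c(regions = length(regions),
               selected_regions = length(sel_regions),
               significant_variants = nrow(sig),
               pruned_variants = nrow(pruned),
               coloc_pairs = nrow(coloc_tbl),
               twas_pairs = nrow(twas_tbl),
               mr_ge_pe_tests = nrow(mr_ge_pe_res),
               mr_pe_cad_tests = nrow(pe_cad),
               chains = nrow(chains)),
    hfdr = hfdr,
    leads = leads,
    pruned = pruned,
    coloc = coloc_tbl,
    direction = direction_tbl,
    twas = twas_tbl,
    mr_ge_pe = mr_ge_pe_res,
    mr_pe_cad = pe_cad,
    sets = list(mx_negative = sort(mx_negative),
                mr_negative = sort(mr_negative),
                qtl_discordant = sort(qtl_discordant),
                center = center),
    overlap = overlap,
    chains = chains,
    truth = truth), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$version, " seed", x$seed, "\n")
  print(x$counts)
  cat("central overlap:", if (length(x$sets$center))
    paste(x$sets$center, collapse = ", ") else "(empty)", "\n")
  invisible(x)
}

#' Write a run report's tables to disk
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return The report, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) if (!is.null(x) && nrow(x))
    readr::write_tsv(x, file.path(out_dir, f))
  w(report$hfdr$regions, "regions_hfdr.tsv")
  w(report$leads, "lead_pqtls.tsv")
  w(report$pruned, "pruned_variants.tsv")
  w(report$coloc, "coloc.tsv")
  w(report$direction, "direction.tsv")
  w(report$twas, "twas.tsv")
  w(report$mr_ge_pe, "mr_ge_pe.tsv")
  w(report$mr_pe_cad, "mr_pe_cad.tsv")
  w(report$chains, "chains.tsv")
  yaml::write_yaml(list(config_hash = report$config_hash,
                        seed = report$seed, version = report$version,
                        counts = as.list(report$counts),
                        sets = report$sets),
                   file.path(out_dir, "report.yaml"))
  invisible(report)
}
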