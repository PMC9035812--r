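# End-to-end synthetic pipeline: simulate -> scan -> depth -> qc -> diversity
# -> het-accuracy -> linkage/qtl, with every table written to disk and a
# manifest capturing config, seed, package version and per-file checksums.
# Re-running with the same config reproduces byte-identical tables.

#' Default pipeline configuration
#'
#' One flat ledger of every stage parameter; no stage has hidden defaults
#' outside this list. Thresholds default to the conventional values of the
#' analysis this package mirrors: depth masks DP < 10 (F2) and DP <= 5 (RIL),
#' genotype-rate cutoffs 0.97 / 0.95, panel filters `DP >= 5`, site quality
#' 30, no heterozygous calls, diversity denominator DP >= 5, 1,000
#' permutations at alpha 0.05 for the LOD threshold (scaled down here for
#' desk-scale determinism), and a reference map of 3,257 markers at diversity
#' 0.002548 for the marker-count extrapolation.
#'
#' @param seed global integer seed.
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genome = list(length_bp = 2e5, n_chromosomes = 2L, ssr_density = 150,
                  repeat_range = c(8L, 14L)),
    panel = list(n_accessions = 6L, pi = 0.0025,
                 groups = c(rep("grp1", 3), rep("grp2", 3))),
    cross = list(f2_progeny = 127L, ril_progeny = 176L, ril_generation = 6L,
                 cM_per_Mb = 3),
    coverage = list(overdispersion = 1, insert_range = c(350L, 800L),
                    read_length = 150L, base_error_rate = 0),
    reads = list(n_read_pairs = 20000L),
    depth = list(min_dp = 10L),
    diversity = list(min_dp = 5L, target_markers = 1000L,
                     ref_markers = 3257L, ref_pi = 0.002548),
    het_accuracy = list(read_fractions = c(1, 2, 3, 4, 5, 6) / 6,
                        n_replicates = 8L, min_dp_grid = 1:20),
    qtl = list(effect = 2, noise_sd = 3.06, n_perm = 200L, alpha = 0.05),
    stages = list(scan = TRUE, depth = TRUE, qc = TRUE, diversity = TRUE,
                  het_accuracy = TRUE, linkage = TRUE, qtl = TRUE)
  ), class = "pipeline_config")
}

# recursively overlay user values onto the default config
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Write report tables
#'
#' Writes each table as a TSV with a fixed dialect plus a JSON summary of row
#' and column counts.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_report <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  bad <- names(tables)[!vapply(tables, is.data.frame, logical(1))]
  if (length(bad)) {
    stop(sprintf("schema violation: not a data.frame: %s",
                 paste(bad, collapse = ", ")))
  }
  for (nm in names(tables)) {
    cols <- names(tables[[nm]])
    if (length(cols) == 0 || anyDuplicated(cols)) {
      stop(sprintf("schema violation in table '%s': columns [%s]", nm,
                   paste(cols, collapse = ", ")))
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- setNames(file.path(dir, paste0(names(tables), ".tsv")),
                    names(tables))
  for (nm in names(tables)) write_tsv(tables[[nm]], paths[[nm]])
  summary <- lapply(tables, function(t) list(rows = nrow(t),
                                             cols = names(t)))
  jsonlite::write_json(summary, file.path(dir, "report_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Run the full synthetic pipeline
#'
#' Executes every enabled stage on synthetic data and writes report tables,
#' data files (FASTA/BED/VCF/depth TSVs) and a `manifest.json` with the
#' config, seed, package version and MD5 checksum of every written file.
#' Deterministic: the same config yields byte-identical outputs.
#'
#' @param config a [default_config()] (possibly modified).
#' @param out_dir output directory.
#' @return list with `tables`, `manifest` and `files`, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         out_dir = tempfile("migseqr_run_")) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  tables <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    genome <- simulate_genome(config$genome$length_bp,
                              config$genome$n_chromosomes,
                              config$genome$ssr_density,
                              repeat_range = config$genome$repeat_range,
                              seed = derive_seed(seed, 1L))
    panel <- simulate_panel(genome, config$panel$n_accessions,
                            config$panel$pi, seed = derive_seed(seed, 2L))
    model <- coverage_model(config$coverage$overdispersion,
                            config$coverage$insert_range,
                            config$coverage$read_length,
                            config$coverage$base_error_rate)
    pd <- simulate_migseq_depths(genome, panel, model,
                                 config$reads$n_read_pairs,
                                 seed = derive_seed(seed, 3L))
    f2 <- simulate_cross(panel$accessions[[1]], panel$accessions[[2]], "F2",
                         config$cross$f2_progeny, genome$chrom_lengths,
                         cM_per_Mb = config$cross$cM_per_Mb,
                         seed = derive_seed(seed, 4L))
    ril <- simulate_cross(panel$accessions[[1]], panel$accessions[[2]], "RIL",
                          config$cross$ril_progeny, genome$chrom_lengths,
                          generation = config$cross$ril_generation,
                          cM_per_Mb = config$cross$cM_per_Mb,
                          seed = derive_seed(seed, 5L))
    qtl_marker <- ceiling(ncol(ril$genotypes) / 2)
    pheno <- simulate_phenotype(
      ril, data.frame(marker = qtl_marker, effect = config$qtl$effect),
      noise_sd = config$qtl$noise_sd, seed = derive_seed(seed, 6L))
    list(genome = genome, panel = panel, depths = pd, f2 = f2, ril = ril,
         pheno = pheno, qtl_marker = qtl_marker)
  })
  note("simulate: genome %d bp, %d SSR loci, %d accessions, %d variant sites",
       sim$genome$length_bp, nrow(sim$genome$ssr_loci),
       config$panel$n_accessions, n_sites(sim$depths$matrix))

  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_bed(sim$genome$ssr_loci, file.path(out_dir, "ssr_truth.bed"))
  write_vcf(sim$depths$matrix, file.path(out_dir, "panel.vcf"),
            sim$genome$chrom_lengths)
  for (s in names(sim$depths$depths)) {
    write_depth_table(sim$depths$depths[[s]],
                      file.path(out_dir, paste0("depth_", s, ".tsv")))
  }
  write_tsv(sim$pheno, file.path(out_dir, "phenotype.tsv"))

  # --- ssr scan ---------------------------------------------------------
  if (isTRUE(config$stages$scan)) {
    tables$ssr_summary <- stage("scan", {
      loci <- scan_ssrs(sim$genome$sequences)
      cnt <- count_targeted_ssrs(loci)
      truth_cnt <- count_targeted_ssrs(sim$genome$ssr_loci)
      write_bed(loci, file.path(out_dir, "ssr_scanned.bed"))
      data.frame(metric = c("genome_size_bp", "scanned_targeted_ssrs",
                            "truth_targeted_ssrs",
                            paste0("scanned_", names(cnt$counts))),
                 value = c(sim$genome$length_bp, cnt$total, truth_cnt$total,
                           unname(cnt$counts)))
    })
    note("scan: %d targeted SSR loci detected",
         tables$ssr_summary$value[2])
  }

  # --- depth profile ----------------------------------------------------
  if (isTRUE(config$stages$depth)) {
    tables$depth_summary <- stage("depth", {
      rows <- lapply(names(sim$depths$depths), function(s) {
        pbd <- sim$depths$depths[[s]]
        mbc <- mapped_base_count(pbd, config$depth$min_dp)
        data.frame(sample = s, min_dp = config$depth$min_dp,
                   mapped_base_count = mbc,
                   per_half_gb = normalize_per_half_gb(mbc, pbd$raw_read_gb))
      })
      do.call(rbind, rows)
    })
    tables$variant_dp <- stage("depth", variant_dp_summary(sim$depths$matrix))
    note("depth: mean mapped base count %.0f",
         mean(tables$depth_summary$mapped_base_count))
  }

  # --- genotype qc ------------------------------------------------------
  if (isTRUE(config$stages$qc)) {
    tables$qc_summary <- stage("qc", {
      qc <- run_qc(sim$depths$matrix, "panel")
      data.frame(population = "panel",
                 sites_in = n_sites(sim$depths$matrix),
                 sites_out = n_sites(qc$matrix),
                 individuals_removed = length(qc$removed_individuals))
    })
    note("qc: panel %d -> %d sites", tables$qc_summary$sites_in,
         tables$qc_summary$sites_out)
  }

  # --- diversity --------------------------------------------------------
  if (isTRUE(config$stages$diversity)) {
    labels <- setNames(config$panel$groups,
                       names(sim$panel$accessions))
    dv <- stage("diversity", {
      pairwise_diversity(sim$depths$matrix, sim$depths$depths,
                         min_dp = config$diversity$min_dp, labels = labels)
    })
    tables$pair_diversity <- dv
    thr <- predict_min_diversity(config$diversity$target_markers,
                                 config$diversity$ref_markers,
                                 config$diversity$ref_pi)
    tables$diversity_threshold <- data.frame(
      target_markers = config$diversity$target_markers,
      ref_markers = config$diversity$ref_markers,
      ref_pi = config$diversity$ref_pi, predicted_min_pi = thr)
    tables$diversity_by_group <- summarize_by_group(dv, labels, thr)
    note("diversity: %d pairs, mean pi %.5g, threshold %.6g", nrow(dv),
         mean(dv$pi, na.rm = TRUE), thr)
  }

  # --- het accuracy -----------------------------------------------------
  if (isTRUE(config$stages$het_accuracy)) {
    tables$het_accuracy <- stage("het_accuracy", {
      mk <- site_keys(sim$depths$matrix)
      pa <- sim$depths$matrix$dp[, 1]
      pb <- sim$depths$matrix$dp[, 2]
      names(pa) <- names(pb) <- mk
      poly <- sim$depths$matrix$gt[, 1] != sim$depths$matrix$gt[, 2]
      poly[is.na(poly)] <- FALSE
      levels <- pmax(1L, as.integer(round(
        config$het_accuracy$read_fractions * min(sum(pa), sum(pb)))))
      virtual_f1_grid(pa[poly], pb[poly], levels,
                      total_reads_a = sum(pa), total_reads_b = sum(pb),
                      n_replicates = config$het_accuracy$n_replicates,
                      min_dp = config$het_accuracy$min_dp_grid,
                      seed = derive_seed(seed, 7L))
    })
    note("het_accuracy: %d grid rows", nrow(tables$het_accuracy))
  }

  # --- linkage ----------------------------------------------------------
  if (isTRUE(config$stages$linkage)) {
    lk <- stage("linkage", {
      f2map <- build_linkage_map(sim$f2$genotypes, sim$f2$markers, "F2")
      rilg <- sim$ril$genotypes
      rilg[rilg == 1L] <- NA_integer_
      rilmap <- build_linkage_map(rilg, sim$ril$markers, "RIL")
      s1 <- map_summary(f2map$map)
      s2 <- map_summary(rilmap$map)
      seg <- segregation_distortion(sim$f2$genotypes, c(1, 2, 1))
      list(summary = data.frame(
        population = c("F2", "RIL"),
        total_cM = c(s1$total_cM, s2$total_cM),
        n_markers = c(s1$n_markers, s2$n_markers),
        n_groups = c(s1$n_groups, s2$n_groups),
        avg_spacing_cM = c(s1$avg_spacing_cM, s2$avg_spacing_cM)),
        two_point = f2map$two_point, distortion = seg)
    })
    tables$map_summary <- lk$summary
    tables$two_point_f2 <- lk$two_point
    tables$segregation_distortion <- lk$distortion
    note("linkage: F2 %.1f cM / %d markers", lk$summary$total_cM[1],
         lk$summary$n_markers[1])
  }

  # --- qtl scan ---------------------------------------------------------
  if (isTRUE(config$stages$qtl)) {
    tables$lod_profile <- stage("qtl", {
      rilg <- sim$ril$genotypes
      rilg[rilg == 1L] <- NA_integer_
      colnames(rilg) <- paste(sim$ril$markers$chrom, sim$ril$markers$pos,
                              sep = ":")
      y <- sim$pheno$phenotype
      prof <- lod_scan(rilg, y)
      thr <- permutation_threshold(rilg, y, n_perm = config$qtl$n_perm,
                                   alpha = config$qtl$alpha,
                                   seed = derive_seed(seed, 8L))
      prof$threshold <- as.numeric(thr)
      prof$causal <- seq_len(nrow(prof)) == sim$qtl_marker
      prof
    })
    peak <- tables$lod_profile[which.max(tables$lod_profile$lod), ]
    note("qtl: peak LOD %.2f at %s (threshold %.2f)", peak$lod, peak$marker,
         peak$threshold)
  }

  paths <- write_report(tables, out_dir)
  writeLines(log, file.path(out_dir, "pipeline.log"))
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  checksums <- tools::md5sum(files)
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    package = "migseqr",
    version = as.character(utils::packageVersion("migseqr")),
    seed = seed, config = unclass(config),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tables = tables, manifest = manifest,
                 files = c(files, file.path(out_dir, "manifest.json"))))
}
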