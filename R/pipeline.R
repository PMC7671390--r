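# End-to-end orchestration: simulate -> consensus -> call -> assemble ->
# refscan -> unify -> enrich -> hotspots -> date, with a JSON manifest.

#' Default pipeline configuration (the demo cohort)
#'
#' @param outdir Ignored here; passed to [run_pipeline()].
#' @return Nested list understood by [run_pipeline()].
#' @export
demo_config <- function(outdir = NULL) {
  list(
    seed = 1L,
    frame = "human",
    tree = "((human:6,chimp:6)hominini:19,macaque:25)catarrhini;",
    samples = demo_samples(),
    sim = list(),          # sim_config() overrides
    plant = list(),        # plant_params() overrides
    caller = list(min_support = 4L, min_mapq = 20L, merge_window = 500L),
    genes = list(n_genes = 15L),
    hotspots = list(bin_width = 250000L, n_perm = 200L, fdr = 0.05),
    enrichment = list(n_sets = 1000L),
    stages = c("simulate", "consensus", "call", "assemble", "refscan",
               "unify", "enrich", "hotspots", "date")
  )
}

#' Synthetic mtDNA gene track
#'
#' Non-overlapping genes around the circle (log-normal lengths ~ 700 bp,
#' ~100 bp intergenic gaps); the last gene wraps the origin, mirroring a
#' D-loop-style control region.
#'
#' @param mt_len mtDNA length.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return data.frame `name`, `start`, `end` (0-based half-open,
#'   circular).
#' @export
make_mt_genes <- function(mt_len, n_genes = 15L, seed = 1L) {
  with_seed(seed, {
    lens <- pmin(pmax(round(stats::rlnorm(n_genes, log(700), 0.4)), 200L),
                 floor(mt_len / n_genes) + 400L)
    gaps <- pmax(round(stats::rnorm(n_genes, 100, 20)), 20L)
    total <- sum(lens) + sum(gaps)
    scale <- mt_len / total
    lens <- pmax(100L, as.integer(floor(lens * scale)))
    gaps <- pmax(10L, as.integer(floor(gaps * scale)))
    start <- mt_len - as.integer(floor(lens[1L] / 2))  # first gene wraps
    out <- data.frame(name = sprintf("GENE%02d", seq_len(n_genes)),
                      start = integer(n_genes), end = integer(n_genes))
    pos <- start
    for (k in seq_len(n_genes)) {
      out$start[k] <- pos %% mt_len
      pos <- pos + lens[k]
      out$end[k] <- pos %% mt_len
      pos <- pos + gaps[k]
    }
    out
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order, writes per-stage outputs
#' under `outdir`, and returns (and writes) a run manifest recording the
#' configuration, seeds, output paths, record counts and MD5 checksums.
#' A stage subset may be requested via `config$stages`; stages whose
#' upstream outputs are absent fail with the missing stage named.
#'
#' @param config Configuration list (see [demo_config()]) or a YAML file
#'   path.
#' @param outdir Output directory.
#' @return The manifest (list), invisibly written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = demo_config(), outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- demo_config()
  for (nm in names(base)) if (is.null(config[[nm]])) config[[nm]] <- base[[nm]]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(tool = "numtforge",
                   version = as.character(utils::packageVersion("numtforge")),
                   seed = config$seed, config = config, stages = list())

  tree <- species_tree(config$tree)
  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  params <- do.call(plant_params, config$plant)
  samples <- config$samples
  cohort <- simulate_cohort(tree, samples, cfg, params, frame = config$frame)
  species <- names(samples)
  all_samples <- sort(unlist(samples, use.names = FALSE))
  sam_path <- function(sm) file.path(outdir, "sams", paste0(sm, ".sam"))

  stage_t0 <- Sys.time()
  record <- function(stage, paths, counts) {
    paths <- unlist(paths)
    manifest$stages[[stage]] <<- list(
      outputs = as.list(paths),
      md5 = as.list(tools::md5sum(paths)),
      counts = as.list(counts),
      elapsed_s = round(as.numeric(Sys.time() - stage_t0,
                                   units = "secs"), 2))
    stage_t0 <<- Sys.time()
  }
  need <- function(stage, path, produced_by) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' requires '", basename(path),
           "' produced by stage '", produced_by, "'; run it first")
    }
    path
  }

  if ("simulate" %in% stages) {
    paths <- write_cohort(cohort, outdir, sams = TRUE)
    record("simulate", paths,
           list(n_numts = nrow(cohort$truth),
                n_samples = length(all_samples),
                sam_records = sum(vapply(all_samples, function(sm) {
                  length(readLines(sam_path(sm))) }, 0L))))
  }

  if ("consensus" %in% stages) {
    paths <- list(); n_changed <- 0L
    for (sm in all_samples) {
      sp <- sample_species(cohort, sm)
      cons <- build_consensus_mt(need("consensus", sam_path(sm), "simulate"),
                                 cohort$lineage$sequences[[sp]],
                                 mt_contig = mt_contig_name(sp))
      out_fa <- file.path(outdir, paste0(sm, "_mt_consensus.fa"))
      ss <- Biostrings::DNAStringSet(cons$sequence)
      names(ss) <- paste0(sm, "_MT")
      Biostrings::writeXStringSet(ss, out_fa)
      aug <- file.path(outdir, paste0(sm, "_augmented.fa"))
      augment_reference(file.path(outdir, paste0(sp, ".fa")), cons,
                        paste0(sm, "_MT_consensus"), aug)
      n_changed <- n_changed +
        str_mismatches(cons$sequence, cohort$lineage$sequences[[sp]])
      paths[[sm]] <- out_fa; paths[[paste0(sm, "_aug")]] <- aug
    }
    record("consensus", paths, list(consensus_positions_changed = n_changed))
  }

  species_calls <- list()
  if ("call" %in% stages) {
    paths <- list(); n_calls <- 0L
    for (sp in species) {
      per_sample <- list()
      for (sm in samples[[sp]]) {
        per_sample[[sm]] <- call_numts(
          need("call", sam_path(sm), "simulate"), mt_contig_name(sp), sm,
          min_mapq = config$caller$min_mapq,
          mt_seq = cohort$lineage$sequences[[sp]],
          insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd,
          min_support = config$caller$min_support)
      }
      merged <- merge_samples(per_sample,
                              window = config$caller$merge_window)
      species_calls[[sp]] <- merged
      bed <- file.path(outdir, paste0(sp, "_calls.bed"))
      vcf <- file.path(outdir, paste0(sp, "_calls.vcf"))
      write_calls(merged, bed = bed, vcf = vcf, species = sp)
      paths[[paste0(sp, "_bed")]] <- bed
      paths[[paste0(sp, "_vcf")]] <- vcf
      n_calls <- n_calls + nrow(merged)
    }
    record("call", paths, list(n_species_calls = n_calls))
  }

  annots <- list()
  if ("assemble" %in% stages) {
    paths <- list(); n_ann <- 0L
    for (sp in species) {
      calls <- get_calls(species_calls, sp, outdir, "assemble")
      sams <- stats::setNames(lapply(samples[[sp]], sam_path),
                              samples[[sp]])
      ann <- assemble_calls(calls, sams, cohort$lineage$sequences[[sp]],
                            mt_contig_name(sp), cohort$ref_seq[[sp]])
      annots[[sp]] <- ann
      tsv <- file.path(outdir, paste0(sp, "_annotations.tsv"))
      utils::write.table(ann, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fa <- file.path(outdir, paste0(sp, "_contigs.fa"))
      ok <- !is.na(ann$best_contig)
      ss <- Biostrings::DNAStringSet(ann$best_contig[ok])
      names(ss) <- paste0(sp, "_", ann$chrom[ok], "_", ann$pos[ok])
      Biostrings::writeXStringSet(ss, fa)
      paths[[paste0(sp, "_tsv")]] <- tsv
      paths[[paste0(sp, "_fa")]] <- fa
      n_ann <- n_ann + sum(ok)
    }
    record("assemble", paths, list(n_annotated = n_ann))
  }

  ref_numts <- list()
  if ("refscan" %in% stages) {
    paths <- list(); n_ref <- 0L
    for (sp in unique(c(species, config$frame))) {
      rn <- scan_reference(cohort$ref_seq[[sp]],
                           cohort$lineage$sequences[[sp]])
      ref_numts[[sp]] <- rn
      bed <- file.path(outdir, paste0(sp, "_reference_numts.bed"))
      utils::write.table(
        data.frame(rn$chrom, rn$start, rn$end,
                   sprintf("REF_%s_%d", rn$chrom, rn$start),
                   round(rn$identity), rn$strand, rn$mt_start, rn$mt_end,
                   rn$fragments),
        bed, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
      paths[[sp]] <- bed
      n_ref <- n_ref + nrow(rn)
    }
    record("refscan", paths, list(n_reference_numts = n_ref))
  }

  unified <- list()
  if ("unify" %in% stages) {
    paths <- list()
    for (sp in species) {
      calls <- get_calls(species_calls, sp, outdir, "unify")
      chain <- read_chain(need(
        "unify", file.path(outdir, paste0(sp, "To", config$frame, ".chain")),
        "simulate"))
      poly <- unify_calls(calls, chain, sp, "polymorphic")
      rn <- ref_numts[[sp]]
      fx <- if (!is.null(rn) && nrow(rn)) {
        u <- liftover_intervals(
          data.frame(chrom = rn$chrom, start = rn$start, end = rn$end),
          chain)
        data.frame(species = sp, class = "fixed", chrom = rn$chrom,
                   pos = rn$start, status = u$status, h_chrom = u$h_chrom,
                   h_pos = u$h_start, stringsAsFactors = FALSE)
      } else NULL
      unified[[sp]] <- rbind(poly, fx)
    }
    # frame species: reference NumtS already in frame coordinates
    rn <- ref_numts[[config$frame]]
    if (!is.null(rn) && nrow(rn)) {
      unified[[config$frame]] <- data.frame(
        species = config$frame, class = "fixed", chrom = rn$chrom,
        pos = rn$start, status = "mapped", h_chrom = rn$chrom,
        h_pos = rn$start, stringsAsFactors = FALSE)
    }
    ub <- do.call(rbind, unified)
    bed <- file.path(outdir, "unified_calls.bed")
    ok <- ub$status == "mapped"
    utils::write.table(
      data.frame(ub$h_chrom[ok], ub$h_pos[ok], ub$h_pos[ok] + 1L,
                 paste0(ub$species[ok], ":", ub$class[ok], ":",
                        ub$chrom[ok], ":", ub$pos[ok])),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    sm_tsv <- file.path(outdir, "sharing_matrix.tsv")
    shm <- sharing_matrix(unified)
    utils::write.table(shm, sm_tsv, sep = "\t", quote = FALSE)
    nodes <- ancestral_nodes(unified, tree, frame = config$frame)
    nodes_json <- file.path(outdir, "ancestral_nodes.json")
    jsonlite::write_json(lapply(nodes, function(x) {
      list(node = x$node, time = x$time, clade = x$clade, count = x$count)
    }), nodes_json, auto_unbox = TRUE, digits = NA)
    record("unify", list(bed = bed, sharing = sm_tsv, nodes = nodes_json),
           list(n_unified = sum(ok),
                n_failed = sum(!ok)))
    paths <- NULL
  }

  if ("enrich" %in% stages) {
    genes <- make_mt_genes(cfg$mt_length, config$genes$n_genes,
                           seed = config$seed)
    paths <- list()
    for (sp in species) {
      ann <- get_annots(annots, sp, outdir, "enrich")
      seg <- ann[!is.na(ann$mt_start), c("mt_start", "mt_end"), drop = FALSE]
      if (!nrow(seg)) next
      z <- gene_enrichment(seg, genes, cfg$mt_length,
                           n_sets = config$enrichment$n_sets,
                           seed = config$seed, include_trna = TRUE)
      tsv <- file.path(outdir, paste0(sp, "_gene_enrichment.tsv"))
      utils::write.table(z, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[sp]] <- tsv
    }
    gb <- file.path(outdir, "mt_genes.bed")
    utils::write.table(data.frame("MT", genes$start, genes$end, genes$name,
                                  0L, "+"),
                       gb, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths$genes <- gb
    record("enrich", paths, list(n_genes = nrow(genes)))
  }

  if ("hotspots" %in% stages) {
    if (!length(unified)) {
      need("hotspots", file.path(outdir, "unified_calls.bed"), "unify")
      unified <- read_unified_bed(file.path(outdir, "unified_calls.bed"))
    }
    seql <- vapply(cohort$ref_seq[[config$frame]], nchar, 0L)
    bt <- bin_frequencies(unified, seql,
                          bin_width = config$hotspots$bin_width)
    hs <- find_hotspots(bt, n_perm = config$hotspots$n_perm,
                        fdr = config$hotspots$fdr, seed = config$seed)
    tsv <- file.path(outdir, "hotspots.tsv")
    utils::write.table(hs, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hb <- file.path(outdir, "hotspots.bed")
    flag <- hs[hs$is_hotspot, , drop = FALSE]
    utils::write.table(data.frame(flag$chrom, flag$start, flag$end,
                                  sprintf("HOTSPOT_%.2f", flag$D)),
                       hb, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    record("hotspots", list(tsv = tsv, bed = hb),
           list(n_hotspots = sum(hs$is_hotspot)))
  }

  if ("date" %in% stages) {
    paths <- list(); all_ages <- list()
    for (sp in species) {
      ann <- get_annots(annots, sp, outdir, "date")
      par <- node_parent(tree, sp)
      T_div <- divergence_time(tree, par)
      prof <- build_profile(cohort$lineage$sequences[[par]],
                            cohort$lineage$sequences[[sp]], T_div, sp)
      rows <- list()
      for (i in seq_len(nrow(ann))) {
        if (is.na(ann$best_contig[i])) next
        d <- date_numt(ann$best_contig[i], cohort$lineage$sequences[[sp]],
                       prof)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(species = sp, chrom = ann$chrom[i],
                           pos = ann$pos[i]), d)
      }
      ages <- do.call(rbind, rows)
      all_ages[[sp]] <- ages
      tsv <- file.path(outdir, paste0(sp, "_ages.tsv"))
      utils::write.table(ages, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[sp]] <- tsv
      ok <- !is.na(ann$best_contig)
      chr <- characterize_numts(
        stats::setNames(ann$best_contig[ok],
                        paste0(ann$chrom[ok], ":", ann$pos[ok])),
        mt_seq = cohort$lineage$sequences[[sp]])
      ctsv <- file.path(outdir, paste0(sp, "_characterization.tsv"))
      utils::write.table(chr$table, ctsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0(sp, "_char")]] <- ctsv
    }
    aa <- do.call(rbind, all_ages)
    n_dated <- sum(!is.na(aa$age))
    record("date", paths, list(n_dated = n_dated))
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# fall back to on-disk outputs when an upstream stage was not run in this
# invocation
get_calls <- function(species_calls, sp, outdir, stage) {
  if (!is.null(species_calls[[sp]])) return(species_calls[[sp]])
  bed <- file.path(outdir, paste0(sp, "_calls.bed"))
  if (!file.exists(bed)) {
    stop("stage '", stage, "' requires calls for ", sp,
         " produced by stage 'call'; run it first")
  }
  b <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = b[[1L]], pos = b[[2L]], ci_lo = b[[7L]],
             ci_hi = b[[8L]], orientation = b[[6L]], support = b[[5L]],
             n_discordant = b[[9L]], n_clipped = b[[10L]],
             carriers = b[[11L]], stringsAsFactors = FALSE)
}

get_annots <- function(annots, sp, outdir, stage) {
  if (!is.null(annots[[sp]])) return(annots[[sp]])
  tsv <- file.path(outdir, paste0(sp, "_annotations.tsv"))
  if (!file.exists(tsv)) {
    stop("stage '", stage, "' requires annotations for ", sp,
         " produced by stage 'assemble'; run it first")
  }
  utils::read.table(tsv, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

read_unified_bed <- function(bed) {
  b <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  tags <- strsplit(b[[4L]], ":")
  df <- data.frame(h_chrom = b[[1L]], h_pos = b[[2L]],
                   species = vapply(tags, `[`, "", 1L),
                   class = vapply(tags, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  split(df, df$species)
}
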