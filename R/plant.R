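#' Default random-draw parameters for Numt planting
#'
#' The defaults describe the reference cohort: 15 polymorphic NumtS per
#' sampled species (30 in the two-species demo), 10 fixed NumtS split
#' between the species references (3 per sampled species, 2 on the frame
#' lineage and 2 ancestral on the internal branch shared by frame and its
#' sister species). Polymorphic lengths are log-normal around 300 bp
#' (recently inserted NumtS are predominantly sub-kilobase), fixed lengths
#' log-normal around 800 bp; polymorphic ages are exponential with mean
#' 1.2 MY (most recent insertions are young); fixed ages are capped at
#' 10 MY so catalogued fixed events stay within the 80% identity floor of
#' the reference scan. Carrier frequencies follow Beta(0.5, 1.5),
#' conditioned on at least one carrier, producing both sample-specific and
#' widely shared events.
#'
#' @param n_poly_per_species Polymorphic NumtS per species with samples.
#' @param n_fixed_per_species Fixed NumtS per sampled species reference.
#' @param n_fixed_frame Fixed NumtS private to the frame species.
#' @param n_ancestral Fixed NumtS per non-root internal branch (inherited
#'   by every descendant species).
#' @param poly_len_meanlog,poly_len_sdlog,poly_len_range Polymorphic
#'   length model (log-normal, clamped).
#' @param fixed_len_meanlog,fixed_len_sdlog,fixed_len_range Fixed length
#'   model.
#' @param poly_age_mean Mean of the exponential polymorphic age (MY).
#' @param fixed_age_max Upper cap on fixed insertion age (MY).
#' @param carrier_beta Two shape parameters of the carrier-frequency Beta.
#' @param min_separation Minimum spacing between planted loci (bp).
#' @param margin Exclusion zone at chromosome ends (bp).
#' @return List of class `plant_params`.
#' @export
plant_params <- function(n_poly_per_species = 15L,
                         n_fixed_per_species = 3L,
                         n_fixed_frame = 2L,
                         n_ancestral = 2L,
                         poly_len_meanlog = log(300), poly_len_sdlog = 0.55,
                         poly_len_range = c(150L, 2500L),
                         fixed_len_meanlog = log(800), fixed_len_sdlog = 0.7,
                         fixed_len_range = c(200L, 5000L),
                         poly_age_mean = 1.2,
                         fixed_age_max = 10,
                         carrier_beta = c(0.5, 1.5),
                         min_separation = 5000L,
                         margin = 10000L) {
  p <- as.list(environment())
  class(p) <- "plant_params"
  p
}

#' Plant fixed and polymorphic NumtS into the cohort genomes
#'
#' Each planted Numt is a circular mtDNA segment copied from the lineage's
#' sequence as it existed `age` MY ago on the branch where the insertion
#' happened ([mt_sequence_at()]), inserted at a nuclear locus expressed in
#' base-frame coordinates. Fixed NumtS (planted on a tip branch or an
#' internal branch) enter the reference genome of every descendant
#' species; polymorphic NumtS exist only in their carrier samples.
#'
#' @param genomes A [build_genomes()] result.
#' @param lineage An [evolve_mt()] result on the same tree.
#' @param samples Named list: species -> character vector of sample IDs.
#' @param params A [plant_params()] (ignored when `directives` given).
#' @param directives Optional explicit data.frame of plantings with
#'   columns `branch`, `status`, `chrom`, `base_pos`, `mt_start`,
#'   `mt_end`, `strand`, `age`, and (for polymorphic) `carriers`
#'   (comma-separated sample IDs). Loci that fall inside or within
#'   `params$min_separation` of another planted Numt are rejected.
#' @param seed Integer seed.
#' @return Object of class `numt_cohort` holding the event tables, the
#'   materialized reference sequences, the truth tables (`truth`,
#'   `truth_by_species`) and everything needed by
#'   [simulate_alignments()] / [write_cohort()].
#' @export
plant_numts <- function(genomes, lineage, samples,
                        params = plant_params(), directives = NULL,
                        seed = genomes$config$seed) {
  stopifnot(inherits(genomes, "numt_genomes"), inherits(lineage, "mt_lineage"))
  tree <- genomes$tree
  frame <- genomes$frame
  mt_len <- lineage$length
  tips <- tree_species(tree)
  bad_sp <- setdiff(names(samples), tips)
  if (length(bad_sp)) stop("samples given for unknown species: ",
                           paste(bad_sp, collapse = ", "))

  if (is.null(directives)) {
    directives <- with_seed(sub_seed(seed, 23L), {
      draw_directives(tree, frame, samples, params, mt_len)
    })
  }
  d <- validate_directives(directives, tree, samples, mt_len, params,
                           genomes)

  # assign nuclear loci where none given
  d <- with_seed(sub_seed(seed, 29L), assign_loci(d, genomes, params))

  # inserted sequence frozen at insertion time on the insertion branch
  d$length <- circ_length(d$mt_start, d$mt_end, mt_len)
  d$seq <- vapply(seq_len(nrow(d)), function(i) {
    s <- mt_sequence_at(lineage, d$branch[i], d$age[i])
    seg <- circ_extract(s, d$mt_start[i], d$mt_end[i])
    if (d$strand[i] == "-") revcomp(seg) else seg
  }, "")
  d$numt_id <- sprintf("N%03d", seq_len(nrow(d)))

  # event tables per genome: indels + inherited fixed NumtS
  events <- stats::setNames(vector("list", length(tips)), tips)
  for (sp in tips) {
    ev <- genomes$indels[[sp]]
    fixed <- d[d$status == "fixed", , drop = FALSE]
    for (i in seq_len(nrow(fixed))) {
      if (sp %in% node_tips(tree, fixed$branch[i])) {
        ev <- rbind(ev, data.frame(
          chrom = fixed$chrom[i], base_pos = fixed$base_pos[i],
          ins_len = fixed$length[i], del_len = 0L, seq = fixed$seq[i],
          id = fixed$numt_id[i], stringsAsFactors = FALSE
        ))
      }
    }
    ev <- ev[order(ev$chrom, ev$base_pos), , drop = FALSE]
    rownames(ev) <- NULL
    events[[sp]] <- ev
  }

  # materialize reference sequences and chain blocks
  ref_seq <- stats::setNames(vector("list", length(tips)), tips)
  blocks <- stats::setNames(vector("list", length(tips)), tips)
  for (sp in tips) {
    ref_seq[[sp]] <- lapply(stats::setNames(genomes$chroms, genomes$chroms),
      function(ch) apply_events(genomes$base_seq[[ch]],
                                events[[sp]][events[[sp]]$chrom == ch, ]))
    if (sp != frame) {
      blocks[[sp]] <- lapply(stats::setNames(genomes$chroms, genomes$chroms),
        function(ch) chain_blocks(
          events[[sp]][events[[sp]]$chrom == ch, ],
          events[[frame]][events[[frame]]$chrom == ch, ],
          genomes$base_len[[ch]]))
    }
  }

  truth_by_species <- build_truth_by_species(d, events, tree, samples, frame,
                                             genomes)
  structure(list(
    genomes = genomes, lineage = lineage, tree = tree, config = genomes$config,
    frame = frame, samples = samples, params = params,
    truth = d, events = events, ref_seq = ref_seq, blocks = blocks,
    truth_by_species = truth_by_species, mt_len = mt_len
  ), class = "numt_cohort")
}

#' @export
print.numt_cohort <- function(x, ...) {
  cat("numt_cohort:", length(tree_species(x$tree)), "species,",
      sum(lengths(x$samples)), "samples,", nrow(x$truth), "planted NumtS (",
      sum(x$truth$status == "polymorphic"), "polymorphic,",
      sum(x$truth$status == "fixed"), "fixed )\n")
  invisible(x)
}

# ---- internals --------------------------------------------------------

draw_directives <- function(tree, frame, samples, params, mt_len) {
  rows <- list()
  draw_segment <- function(len) {
    len <- min(len, mt_len)
    start <- sample.int(mt_len, 1L) - 1L
    c(start, (start + len) %% mt_len)
  }
  rlen <- function(meanlog, sdlog, range) {
    as.integer(pmin(pmax(round(stats::rlnorm(1, meanlog, sdlog)), range[1]),
                    range[2]))
  }
  add <- function(branch, status, age, len, carriers = "") {
    seg <- draw_segment(len)
    rows[[length(rows) + 1L]] <<- data.frame(
      branch = branch, status = status, chrom = NA_character_,
      base_pos = NA_integer_, mt_start = seg[1], mt_end = seg[2],
      strand = sample(c("+", "-"), 1L), age = age, carriers = carriers,
      stringsAsFactors = FALSE
    )
  }
  for (sp in names(samples)) {
    t_old <- divergence_time(tree, node_parent(tree, sp))
    for (i in seq_len(params$n_poly_per_species)) {
      age <- min(0.05 + stats::rexp(1, 1 / params$poly_age_mean), 0.9 * t_old)
      f <- stats::rbeta(1, params$carrier_beta[1], params$carrier_beta[2])
      k <- stats::rbinom(1, length(samples[[sp]]), f)
      if (k == 0L) k <- 1L
      carriers <- paste(sort(sample(samples[[sp]], k)), collapse = ",")
      add(sp, "polymorphic", age,
          rlen(params$poly_len_meanlog, params$poly_len_sdlog,
               params$poly_len_range), carriers)
    }
    for (i in seq_len(params$n_fixed_per_species)) {
      add(sp, "fixed",
          stats::runif(1, max(0.3 * t_old, 1),
                       min(0.95 * t_old, params$fixed_age_max)),
          rlen(params$fixed_len_meanlog, params$fixed_len_sdlog,
               params$fixed_len_range))
    }
  }
  t_old_frame <- divergence_time(tree, node_parent(tree, frame))
  for (i in seq_len(params$n_fixed_frame)) {
    add(frame, "fixed",
        stats::runif(1, max(0.3 * t_old_frame, 1),
                     min(0.95 * t_old_frame, params$fixed_age_max)),
        rlen(params$fixed_len_meanlog, params$fixed_len_sdlog,
             params$fixed_len_range))
  }
  phy <- tree$phylo
  internal <- phy$node.label[-1L]  # all internal nodes except the root
  for (nd in internal) {
    young <- divergence_time(tree, nd)
    old <- divergence_time(tree, node_parent(tree, nd))
    for (i in seq_len(params$n_ancestral)) {
      add(nd, "fixed",
          stats::runif(1, young + 0.5,
                       min(0.95 * old, max(params$fixed_age_max, young + 2))),
          rlen(params$fixed_len_meanlog, params$fixed_len_sdlog,
               params$fixed_len_range))
    }
  }
  if (!length(rows)) {
    return(data.frame(branch = character(), status = character(),
                      chrom = character(), base_pos = integer(),
                      mt_start = integer(), mt_end = integer(),
                      strand = character(), age = numeric(),
                      carriers = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

validate_directives <- function(d, tree, samples, mt_len, params, genomes) {
  need <- c("branch", "status", "mt_start", "mt_end", "strand", "age")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("directives missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"carriers" %in% names(d)) d$carriers <- ""
  if (!"chrom" %in% names(d)) d$chrom <- NA_character_
  if (!"base_pos" %in% names(d)) d$base_pos <- NA_integer_
  for (i in seq_len(nrow(d))) {
    span <- branch_span(tree, d$branch[i])
    if (d$age[i] < span["young"] - 1e-9 || d$age[i] > span["old"] + 1e-9) {
      stop("numt age ", d$age[i], " outside the span of branch ", d$branch[i])
    }
    if (d$status[i] == "polymorphic") {
      sp <- d$branch[i]
      if (!sp %in% names(samples)) {
        stop("polymorphic numt on species without samples: ", sp)
      }
      carr <- strsplit(d$carriers[i], ",")[[1]]
      if (length(carr) == 0L) stop("polymorphic numt needs >= 1 carrier")
      if (!all(carr %in% samples[[sp]])) {
        stop("unknown carriers for species ", sp)
      }
    }
  }
  if (any(d$mt_start < 0 | d$mt_start >= mt_len |
          d$mt_end < 0 | d$mt_end > mt_len)) {
    stop("mt segment coordinates outside [0, mt length)")
  }
  # explicit loci must not collide with each other
  given <- which(!is.na(d$base_pos))
  if (length(given) > 1L) {
    g <- d[given, ]
    o <- order(g$chrom, g$base_pos)
    g <- g[o, ]
    same <- g$chrom[-1L] == g$chrom[-nrow(g)]
    if (any(same & diff(g$base_pos) < params$min_separation)) {
      stop("requested locus inside or too near another planted Numt")
    }
  }
  d
}

assign_loci <- function(d, genomes, params) {
  chroms <- genomes$chroms
  taken <- d$base_pos[!is.na(d$base_pos)]
  taken_chrom <- d$chrom[!is.na(d$base_pos)]
  avoid <- lapply(stats::setNames(chroms, chroms), function(ch) {
    pos <- unlist(lapply(genomes$indels, function(e) {
      e$base_pos[e$chrom == ch]
    }), use.names = FALSE)
    c(pos, taken[taken_chrom == ch])
  })
  for (i in which(is.na(d$base_pos))) {
    ok <- FALSE
    for (try in 1:1000) {
      ch <- sample(chroms, 1L)
      p <- sample.int(genomes$base_len[[ch]] - 2L * params$margin, 1L) +
        params$margin
      if (all(abs(avoid[[ch]] - p) >= params$min_separation)) {
        d$chrom[i] <- ch; d$base_pos[i] <- p
        avoid[[ch]] <- c(avoid[[ch]], p)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place numt ", i, "; genome too crowded")
  }
  d
}

empty_truth_by_species <- function() {
  data.frame(numt_id = character(), species = character(),
             status = character(), chrom = character(),
             ref_start = integer(), ref_end = integer(), length = integer(),
             mt_start = integer(), mt_end = integer(), strand = character(),
             age = numeric(), human_start = integer(),
             human_end = integer(), carriers = character(),
             stringsAsFactors = FALSE)
}

build_truth_by_species <- function(d, events, tree, samples, frame, genomes) {
  if (!nrow(d)) return(empty_truth_by_species())
  rows <- list()
  for (i in seq_len(nrow(d))) {
    carrier_sp <- if (d$status[i] == "polymorphic") d$branch[i] else
      node_tips(tree, d$branch[i])
    for (sp in carrier_sp) {
      ev <- events[[sp]][events[[sp]]$chrom == d$chrom[i], , drop = FALSE]
      g <- map_base_to_genome(d$base_pos[i], ev)
      in_ref <- d$status[i] == "fixed"
      ref_start <- if (in_ref) g - d$length[i] else g
      ev_f <- events[[frame]][events[[frame]]$chrom == d$chrom[i], ,
                              drop = FALSE]
      h <- map_base_to_genome(d$base_pos[i], ev_f)
      in_frame_ref <- d$status[i] == "fixed" &&
        frame %in% node_tips(tree, d$branch[i])
      human_start <- if (in_frame_ref) h - d$length[i] else h
      carr <- if (d$status[i] == "polymorphic") d$carriers[i] else
        paste(samples[[sp]], collapse = ",")
      rows[[length(rows) + 1L]] <- data.frame(
        numt_id = d$numt_id[i], species = sp, status = d$status[i],
        chrom = d$chrom[i], ref_start = ref_start,
        ref_end = if (in_ref) g else g,
        length = d$length[i], mt_start = d$mt_start[i], mt_end = d$mt_end[i],
        strand = d$strand[i], age = d$age[i],
        human_start = human_start,
        human_end = if (in_frame_ref) h else h,
        carriers = carr, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polymorphic insertions present in one sample's genome
#'
#' @param cohort A [plant_numts()] cohort.
#' @param sample Sample ID.
#' @return data.frame of insertions in reference coordinates, sorted:
#'   `chrom`, `ref_pos` (breakpoint), `length`, `seq`, `mt_start`,
#'   `mt_end`, `strand`, `numt_id`.
#' @export
sample_insertions <- function(cohort, sample) {
  sp <- sample_species(cohort, sample)
  tb <- cohort$truth_by_species
  tb <- tb[tb$species == sp & tb$status == "polymorphic", , drop = FALSE]
  keep <- vapply(strsplit(tb$carriers, ","), function(x) sample %in% x, TRUE)
  tb <- tb[keep, , drop = FALSE]
  d <- cohort$truth[match(tb$numt_id, cohort$truth$numt_id), ]
  out <- data.frame(chrom = tb$chrom, ref_pos = tb$ref_start,
                    length = tb$length, seq = d$seq,
                    mt_start = tb$mt_start, mt_end = tb$mt_end,
                    strand = tb$strand, numt_id = tb$numt_id,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$ref_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_species <- function(cohort, sample) {
  for (sp in names(cohort$samples)) {
    if (sample %in% cohort$samples[[sp]]) return(sp)
  }
  stop("unknown sample: ", sample)
}
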