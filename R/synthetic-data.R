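#' Generate a toy bacterial genome with non-overlapping genes
#'
#' Draws a random nucleotide sequence at a target GC content and places
#' `n_genes` non-overlapping gene models on both strands. The gene table
#' uses 0-based half-open coordinates; the transcriptional start site (TSS)
#' is the start for `+` genes and `end - 1` for `-` genes.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_fraction Target GC content in `[0, 1]`.
#' @param n_genes Number of genes to place (may be 0).
#' @param circular Is the chromosome circular? Default `TRUE`.
#' @param seed Integer seed; all output is a pure function of it.
#' @param gene_length_range Range of gene lengths drawn uniformly, bp.
#'
#' @return A list with `genome` (list: `chrom_id`, `sequence`, `circular`)
#'   and `genes` (tibble: `gene_id`, `start`, `end`, `strand`, `tss`),
#'   sorted by `start`.
#' @export
#' @examples
#' g <- generate_genome(10000, 0.54, n_genes = 5, seed = 1)
#' g$genes
generate_genome <- function(length, gc_fraction, n_genes, circular = TRUE,
                            seed = 1L, gene_length_range = c(600L, 1500L)) {
  stopifnot(length >= 1000, gc_fraction >= 0, gc_fraction <= 1, n_genes >= 0)
  withr_seed(seed)
  probs <- c(
    A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
    G = gc_fraction / 2, T = (1 - gc_fraction) / 2
  )
  sequence <- paste(
    sample(names(probs), length, replace = TRUE, prob = probs),
    collapse = ""
  )

  genes <- tibble::tibble(
    gene_id = character(), start = integer(), end = integer(),
    strand = character(), tss = integer()
  )
  if (n_genes > 0) {
    lens <- sample(seq.int(gene_length_range[1], gene_length_range[2]),
                   n_genes, replace = TRUE)
    if (sum(lens) > length) {
      stop("genome too small to place ", n_genes, " non-overlapping genes")
    }
    starts <- integer(0)
    ends <- integer(0)
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in 1:2000) {
        s <- sample.int(length - lens[i], 1L) - 1L  # keep genes off the origin
        e <- s + lens[i]
        if (!any(s < ends & e > starts)) {
          starts <- c(starts, s); ends <- c(ends, e)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_genes,
             " non-overlapping genes on a genome of length ", length)
      }
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    if (n_genes >= 2 && length(unique(strand)) == 1) {
      strand[1] <- setdiff(c("+", "-"), strand[1])
    }
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]; strand <- strand[ord]
    genes <- tibble::tibble(
      gene_id = sprintf("gene%03d", seq_len(n_genes)),
      start = as.integer(starts), end = as.integer(ends),
      strand = strand,
      tss = as.integer(ifelse(strand == "+", starts, ends - 1L))
    )
  }

  list(
    genome = list(chrom_id = "synthetic_chr", sequence = sequence,
                  circular = isTRUE(circular)),
    genes = genes
  )
}

#' Plant ground-truth binding peaks on a synthetic genome
#'
#' Places `n_peaks` Gaussian-shaped binding sites, an `upstream_fraction` of
#' them in the promoter-proximal window upstream of a gene TSS and the rest
#' inside gene bodies. Each peak carries a height, a width (FWHM of the
#' planted bump) and a condition mask saying under which growth conditions
#' (for example iron excess vs heme) the site is bound. Summits of distinct
#' peaks are kept at least twice the larger of the two widths apart so that
#' planted sites are unambiguous ground truth for recovery tests.
#'
#' @param genome,genes Output components of [generate_genome()].
#' @param n_peaks Number of binding sites to plant.
#' @param height_range Range of peak heights (depth units above background).
#' @param width_range Range of peak FWHM in bp (>= 5).
#' @param upstream_fraction Fraction of peaks placed upstream of a TSS.
#' @param conditions Character vector of condition labels.
#' @param background_mean Background depth used later by
#'   [simulate_coverage()].
#' @param seed Integer seed.
#' @param condition_pattern Optional explicit per-peak condition masks, a
#'   character vector of length `n_peaks` with labels joined by `+`
#'   (e.g. `"iron"`, `"iron+heme"`). Overrides the seeded random masks.
#' @param motif_fraction Fraction of peaks flagged to receive a planted
#'   motif instance via [plant_motif()].
#' @param upstream_window Width of the promoter window used for upstream
#'   placement, bp.
#'
#' @return A `synthetic_truth` list: `genome`, `genes`, `peaks` (tibble:
#'   `peak_id`, `summit`, `height`, `width`, `condition_mask` (list column),
#'   `motif_planted`, `location_class`, `gene_id`), `background_mean`,
#'   `conditions`, `seed`.
#' @export
plant_peaks <- function(genome, genes, n_peaks,
                        height_range = c(30, 300), width_range = c(40, 120),
                        upstream_fraction = 0.8,
                        conditions = c("iron", "heme"),
                        background_mean = 10, seed = 1L,
                        condition_pattern = NULL, motif_fraction = 0,
                        upstream_window = 500L) {
  stopifnot(
    all(height_range > 0), all(width_range >= 5),
    upstream_fraction >= 0, upstream_fraction <= 1,
    length(conditions) >= 1
  )
  L <- nchar(genome$sequence)
  withr_seed(seed)

  peaks <- tibble::tibble(
    peak_id = character(), summit = integer(), height = numeric(),
    width = numeric(), condition_mask = list(), motif_planted = logical(),
    location_class = character(), gene_id = character()
  )
  if (n_peaks > 0) {
    n_up <- round(upstream_fraction * n_peaks)
    if (n_up > 0 && nrow(genes) == 0) {
      stop("upstream placement requested but no genes supplied")
    }
    widths <- stats::runif(n_peaks, width_range[1], width_range[2])
    heights <- stats::runif(n_peaks, height_range[1], height_range[2])

    summits <- integer(0)
    classes <- character(0)
    gene_ids <- character(0)
    for (i in seq_len(n_peaks)) {
      placed <- FALSE
      for (try in 1:5000) {
        if (i <= n_up) {
          g <- genes[sample.int(nrow(genes), 1L), ]
          off <- sample.int(min(upstream_window - 10L, 400L), 1L) + 9L
          s <- if (g$strand == "+") g$tss - off else g$tss + off
          s <- ((s %% L) + L) %% L
          # reject placements that land inside some gene body, which would
          # make the annotation call them intragenic
          if (any(genes$start <= s & s < genes$end)) next
          cls <- "upstream"; gid <- g$gene_id
        } else {
          if (nrow(genes) > 0) {
            g <- genes[sample.int(nrow(genes), 1L), ]
            s <- g$start + sample.int(g$end - g$start, 1L) - 1L
            cls <- "intragenic"; gid <- g$gene_id
          } else {
            s <- sample.int(L, 1L) - 1L
            cls <- "intergenic"; gid <- NA_character_
          }
        }
        sep_ok <- TRUE
        if (length(summits) > 0) {
          need <- 2 * pmax(widths[i], widths[seq_along(summits)])
          sep_ok <- all(
            circ_dist(s, summits, L, genome$circular) >= need
          )
        }
        if (sep_ok) {
          summits <- c(summits, s); classes <- c(classes, cls)
          gene_ids <- c(gene_ids, gid)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("cannot place ", n_peaks, " peaks with separation >= 2*width; ",
             "reduce n_peaks or widths")
      }
    }

    if (is.null(condition_pattern)) {
      masks <- lapply(seq_len(n_peaks), function(i) {
        m <- conditions[stats::runif(length(conditions)) < 0.6]
        if (length(m) == 0) m <- sample(conditions, 1L)
        m
      })
    } else {
      stopifnot(length(condition_pattern) == n_peaks)
      masks <- strsplit(condition_pattern, "+", fixed = TRUE)
      bad <- !vapply(masks, function(m) all(m %in% conditions), logical(1))
      if (any(bad)) stop("condition_pattern contains unknown labels")
    }
    motif <- rep(FALSE, n_peaks)
    if (motif_fraction > 0) {
      motif[sample.int(n_peaks, round(motif_fraction * n_peaks))] <- TRUE
    }
    peaks <- tibble::tibble(
      peak_id = sprintf("peak%03d", seq_len(n_peaks)),
      summit = as.integer(summits), height = heights, width = widths,
      condition_mask = masks, motif_planted = motif,
      location_class = classes, gene_id = gene_ids
    )
  }

  structure(
    list(
      genome = genome, genes = genes, peaks = peaks,
      background_mean = background_mean, conditions = conditions,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d bp genome, %d genes, %d planted peaks, background %g\n",
    nchar(x$genome$sequence), nrow(x$genes), nrow(x$peaks), x$background_mean
  ))
  invisible(x)
}

# Expected (noise-free, unrounded) coverage profile for one condition.
expected_profile <- function(truth, condition) {
  L <- nchar(truth$genome$sequence)
  prof <- rep(truth$background_mean, L)
  pk <- truth$peaks
  if (nrow(pk) > 0) {
    active <- vapply(pk$condition_mask, function(m) condition %in% m,
                     logical(1))
    for (i in which(active)) {
      sigma <- pk$width[i] / 2.355
      r <- ceiling(5 * sigma)
      idx <- wrap_index(pk$summit[i] - r, pk$summit[i] + r + 1, L)
      d <- seq.int(-r, r)
      prof[idx] <- prof[idx] + pk$height[i] * exp(-d^2 / (2 * sigma^2))
    }
  }
  prof
}

#' Simulate a replicate coverage track from planted truth
#'
#' The expected depth at position x is the background mean plus the sum of
#' Gaussian bumps of the peaks active under `condition` (FWHM = planted
#' width; circular distance to the summit). `noise = "none"` returns the
#' expectation rounded to integers; `noise = "poisson"` draws per-base
#' Poisson counts with that mean.
#'
#' @param truth A `synthetic_truth` from [plant_peaks()].
#' @param condition One of `truth$conditions`.
#' @param replicate Replicate number (label only).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed (used for Poisson noise).
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(truth, condition, replicate = 1L,
                              noise = c("poisson", "none"), seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  noise <- match.arg(noise)
  if (!condition %in% truth$conditions) {
    stop("unknown condition '", condition, "'")
  }
  mu <- expected_profile(truth, condition)
  values <- if (noise == "none") {
    round(mu)
  } else {
    withr_seed(seed)
    stats::rpois(length(mu), mu)
  }
  coverage_track(
    values, chrom = truth$genome$chrom_id, circular = truth$genome$circular,
    sample = paste(condition, replicate, sep = "_rep"),
    condition = condition, replicate = replicate
  )
}

#' Overwrite planted summits with a concrete motif instance
#'
#' For every planted peak flagged `motif_planted`, the genome sequence
#' centered on the summit is replaced by one realization of the IUPAC
#' consensus (ambiguity codes resolved randomly under the seed). All other
#' positions are untouched.
#'
#' @param genome Genome list (from [generate_genome()]).
#' @param truth A `synthetic_truth`.
#' @param consensus IUPAC consensus string; must be shorter than the
#'   narrowest planted peak.
#' @param seed Integer seed for ambiguity resolution.
#' @return The genome list with a modified `sequence`.
#' @export
plant_motif <- function(genome, truth, consensus, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  codes <- iupac_table()
  letters_c <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters_c %in% names(codes))) {
    stop("invalid IUPAC code in consensus")
  }
  W <- length(letters_c)
  pk <- truth$peaks[truth$peaks$motif_planted, , drop = FALSE]
  if (nrow(pk) > 0 && W >= min(pk$width)) {
    stop("consensus must be shorter than the narrowest planted peak")
  }
  L <- nchar(genome$sequence)
  seqv <- strsplit(genome$sequence, "")[[1]]
  withr_seed(seed)
  for (i in seq_len(nrow(pk))) {
    start <- pk$summit[i] - W %/% 2
    if (!genome$circular && (start < 0 || start + W > L)) {
      stop("motif would overlap the ends of a linear genome")
    }
    inst <- vapply(letters_c, function(cd) {
      opts <- codes[[cd]]
      if (length(opts) == 1) opts else sample(opts, 1L)
    }, character(1))
    seqv[wrap_index(start, start + W, L)] <- inst
  }
  genome$sequence <- paste(seqv, collapse = "")
  genome
}

#' Simulate a differential-expression table for planted targets
#'
#' Every gene gets a log2 expression ratio. Under the `null` model ratios
#' are independent N(0, `noise_sd`) draws. Under `anti_proportional`, genes
#' owning a planted peak get a ratio whose magnitude decreases with the
#' peak height (higher binding, weaker differential expression), emulating
#' the anti-proportional trend between binding strength and expression
#' change; remaining genes are null draws.
#'
#' @param truth A `synthetic_truth` whose peaks are mapped to their nearest
#'   gene.
#' @param model `"null"` or `"anti_proportional"`.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param seed Integer seed.
#' @param slope Magnitude step per rank in the anti-proportional model.
#' @return Tibble with `gene_id` and `log2_ratio`.
#' @export
simulate_expression <- function(truth, model = c("null", "anti_proportional"),
                                noise_sd = 0.5, seed = 1L, slope = 0.05) {
  stopifnot(inherits(truth, "synthetic_truth"))
  model <- match.arg(model)
  genes <- truth$genes
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), log2_ratio = numeric()))
  }
  withr_seed(seed)
  ratio <- stats::rnorm(nrow(genes), 0, noise_sd)
  if (model == "anti_proportional" && nrow(truth$peaks) > 0) {
    L <- nchar(truth$genome$sequence)
    # each peak -> nearest gene by circular TSS distance; max height per gene
    nearest <- vapply(truth$peaks$summit, function(s) {
      which.min(circ_dist(s, genes$tss, L, truth$genome$circular))
    }, integer(1))
    by_gene <- tapply(truth$peaks$height, nearest, max)
    idx <- as.integer(names(by_gene))
    h <- as.numeric(by_gene)
    n <- length(h)
    # |log2| anti-ranked to height: tallest peak -> smallest magnitude
    mag <- slope * (n + 1 - rank(h, ties.method = "first"))
    ratio[idx] <- -mag + stats::rnorm(n, 0, noise_sd)
  }
  tibble::tibble(gene_id = genes$gene_id, log2_ratio = ratio)
}

#' Write a synthetic truth bundle to disk
#'
#' Writes the genome FASTA, the gene models as GFF3 (1-based inclusive
#' `gene` features with `ID=` attributes), one bedGraph per condition x
#' replicate, and a JSON sidecar holding the planted truth, so that tests
#' and pipelines share a single ground-truth source.
#'
#' @param truth A `synthetic_truth`.
#' @param outdir Output directory (created if needed).
#' @param replicates Replicates per condition.
#' @param noise Noise model passed to [simulate_coverage()].
#' @param seed Integer base seed; replicate r of condition c uses
#'   `seed + 1000*c + r`.
#' @return Invisibly, a named list of written paths.
#' @export
write_truth_bundle <- function(truth, outdir, replicates = 3L,
                               noise = "poisson", seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fasta")
  gff <- file.path(outdir, "genes.gff3")
  js <- file.path(outdir, "truth.json")
  write_genome_fasta(truth$genome, fa)
  write_genes_gff3(truth$genes, truth$genome, gff)

  tracks <- list()
  for (ci in seq_along(truth$conditions)) {
    cond <- truth$conditions[ci]
    for (r in seq_len(replicates)) {
      trk <- simulate_coverage(truth, cond, r, noise = noise,
                               seed = seed + 1000L * ci + r)
      p <- file.path(outdir, sprintf("%s_rep%d.bedgraph", cond, r))
      write_track(trk, p)
      tracks[[trk$sample]] <- p
    }
  }

  pk <- truth$peaks
  pk$condition_mask <- vapply(pk$condition_mask, paste, character(1),
                              collapse = "+")
  jsonlite::write_json(
    list(
      chrom_id = truth$genome$chrom_id,
      genome_length = nchar(truth$genome$sequence),
      circular = truth$genome$circular,
      background_mean = truth$background_mean,
      conditions = truth$conditions, seed = truth$seed,
      genes = truth$genes, peaks = pk
    ),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(list(fasta = fa, gff3 = gff, truth = js), tracks))
}

#' Write a genome as FASTA
#' @param genome Genome list with `chrom_id` and `sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- genome$chrom_id
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a single-chromosome genome from FASTA
#' @param path FASTA path.
#' @param circular Circularity flag to attach (FASTA does not carry it).
#' @return Genome list (`chrom_id`, `sequence`, `circular`).
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) != 1) stop("expected a single-sequence FASTA")
  list(
    chrom_id = sub("\\s.*$", "", names(dna)[1]),
    sequence = as.character(dna[[1]]),
    circular = isTRUE(circular)
  )
}

# GFF3 writer: internal 0-based half-open -> 1-based inclusive on disk.
#' Write gene models as GFF3
#' @param genes Gene tibble (`gene_id`, `start`, `end`, `strand`).
#' @param genome Genome list (for the seqid).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genes_gff3 <- function(genes, genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genome$chrom_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "chapkit"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

iupac_table <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
}

# Every generator is a pure function of its seed.
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
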