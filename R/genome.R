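#' Chromosome specification
#'
#' A karyotype is a data frame of chromosome specifications: a label, a
#' length in megabases (one monomer per Mb in the coarse-grained model) and a
#' copy number (2 for autosomes and for X in the female diploid karyotype).
#'
#' @param name character vector of chromosome labels (unique).
#' @param length_mb integer vector of chromosome lengths in Mb (>= 1).
#' @param copies integer vector of copy numbers (>= 1), recycled.
#' @return A `karyotype` data frame with columns `name`, `length_mb`,
#'   `copies`.
#' @export
karyotype <- function(name, length_mb, copies = 2L) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("chromosome names must be unique within a karyotype")
  }
  length_mb <- as.integer(length_mb)
  copies <- as.integer(rep_len(copies, length(name)))
  if (any(length_mb < 1L)) stop("length_mb must be >= 1")
  if (any(copies < 1L)) stop("copies must be >= 1")
  out <- data.frame(name = name, length_mb = length_mb, copies = copies,
                    stringsAsFactors = FALSE)
  class(out) <- c("karyotype", "data.frame")
  out
}

#' Default diploid female human karyotype at 1 Mb resolution
#'
#' 22 autosomal pairs plus two X chromosomes, coarse grained to whole
#' megabases. Four lengths are fixed by the chromosome pairs the model is
#' usually probed with (chr12 134, chr18 78, chr19 60, chr20 63 Mb); the
#' remaining lengths follow a standard human assembly rounded to Mb, with
#' chromosome 1 absorbing the rounding remainder so that the haploid sum is
#' 3049 Mb and the diploid monomer count is 6098.
#'
#' @return A `karyotype` data frame (23 rows, all with `copies = 2`).
#' @export
human_karyotype <- function() {
  len <- c(chr1 = 264L, chr2 = 243L, chr3 = 198L, chr4 = 191L,
           chr5 = 181L, chr6 = 171L, chr7 = 159L, chr8 = 146L,
           chr9 = 141L, chr10 = 136L, chr11 = 135L, chr12 = 134L,
           chr13 = 115L, chr14 = 107L, chr15 = 102L, chr16 = 90L,
           chr17 = 81L, chr18 = 78L, chr19 = 60L, chr20 = 63L,
           chr21 = 48L, chr22 = 51L, chrX = 155L)
  karyotype(names(len), len, copies = 2L)
}

#' Small tutorial karyotype
#'
#' A reduced system of identical chains used for scaled-down simulations:
#' `n_chains` single-copy chromosomes of `length_mb` monomers each
#' (default 8 x 100 = 800 monomers).
#'
#' @param n_chains number of chains.
#' @param length_mb monomers per chain.
#' @return A `karyotype` data frame.
#' @export
tutorial_karyotype <- function(n_chains = 8L, length_mb = 100L) {
  karyotype(sprintf("chr%02d", seq_len(n_chains)),
            rep(length_mb, n_chains), copies = 1L)
}

validate_track <- function(track) {
  stopifnot(all(c("chrom", "start", "gene_content") %in% names(track)))
  if (any(track$gene_content < 0)) {
    stop("gene content must be non-negative")
  }
  for (ch in unique(track$chrom)) {
    st <- sort(track$start[track$chrom == ch])
    if (anyDuplicated(st)) {
      stop(sprintf("duplicate bin in chromosome %s", ch))
    }
    if (!identical(as.integer(st), seq(0L, length(st) - 1L))) {
      stop(sprintf("non-contiguous bins in chromosome %s", ch))
    }
  }
  track <- track[order(match(track$chrom, unique(track$chrom)), track$start), ,
                 drop = FALSE]
  rownames(track) <- NULL
  class(track) <- c("gene_track", "data.frame")
  track
}

#' Load a gene-density track
#'
#' Reads a BED-like tab-separated file with columns chrom / start(Mb) /
#' end(Mb) / gene_content and an optional header line starting with `#`.
#' Bins must be contiguous, 1 Mb wide, 0-based half-open and unique; gene
#' content must be non-negative.
#'
#' @param path path to the track file.
#' @return A `gene_track` data frame with columns `chrom`, `start`,
#'   `gene_content`.
#' @export
load_gene_track <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("chrom", "start", "end",
                                         "gene_content"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  if (any(raw$end - raw$start != 1L)) {
    stop("bins must be exactly 1 Mb wide")
  }
  validate_track(raw[, c("chrom", "start", "gene_content")])
}

#' Write a gene-density track
#'
#' Inverse of [load_gene_track()]: BED-like tab-separated text with a `#`
#' header line.
#'
#' @param track a `gene_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart_mb\tend_mb\tgene_content", con)
  utils::write.table(
    data.frame(track$chrom, track$start, track$start + 1L,
               format(track$gene_content, digits = 17, trim = TRUE,
                      scientific = FALSE)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Synthesize a gene-density track
#'
#' Draws per-bin gene contents from a heavy-tailed non-negative (log-normal)
#' distribution and rescales each chromosome linearly so that every
#' constrained chromosome's mean gene density (genes/Mb) matches its
#' constraint exactly. Unconstrained chromosomes are rescaled to
#' `default_mean`. The same seed reproduces the same track bit for bit.
#'
#' @param kar a `karyotype`.
#' @param constraints named numeric vector or list mapping chromosome name to
#'   target mean genes/Mb.
#' @param default_mean mean genes/Mb for unconstrained chromosomes.
#' @param sdlog log-normal shape parameter controlling bin-to-bin
#'   heterogeneity (heavier tail for larger values).
#' @param seed integer RNG seed.
#' @return A `gene_track` data frame.
#' @export
synthesize_gene_track <- function(kar, constraints = NULL, default_mean = 27,
                                  sdlog = 1, seed = 1L) {
  constraints <- unlist(constraints)
  if (length(constraints)) {
    unknown <- setdiff(names(constraints), kar$name)
    if (length(unknown)) {
      stop(sprintf("constraint on unknown chromosome(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    if (any(constraints < 0)) stop("constrained means must be >= 0")
  }
  if (default_mean < 0) stop("default_mean must be >= 0")
  withr_seed(seed, {
    pieces <- lapply(seq_len(nrow(kar)), function(i) {
      n <- kar$length_mb[i]
      target <- if (kar$name[i] %in% names(constraints)) {
        constraints[[kar$name[i]]]
      } else {
        default_mean
      }
      x <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
      x <- x * (target / mean(x))
      data.frame(chrom = kar$name[i], start = seq_len(n) - 1L,
                 gene_content = x, stringsAsFactors = FALSE)
    })
    validate_track(do.call(rbind, pieces))
  })
}

#' Packaged default gene-density track (synthetic)
#'
#' A deterministic synthetic stand-in for the gene-content map of the human
#' genome at 1 Mb resolution (per-Mb gene counts from a genome database are
#' not redistributable). Chromosome-mean densities are pinned to the values
#' the model is calibrated against -- chr19 62.03, chr18 18.64, chr12 30.92
#' and chr20 29.71 genes/Mb -- and all other chromosomes get the default
#' mean.
#'
#' @param seed internal seed; fixed so the packaged track is reproducible.
#' @return A `gene_track` covering [human_karyotype()].
#' @export
default_gene_track <- function(seed = 20140122L) {
  synthesize_gene_track(
    human_karyotype(),
    constraints = c(chr12 = 30.92, chr18 = 18.64, chr19 = 62.03,
                    chr20 = 29.71),
    default_mean = 27, sdlog = 1, seed = seed)
}

#' Build the per-monomer table
#'
#' Expands a karyotype and a gene-density track into one row per monomer
#' (one 1 Mb domain per chromosome copy). Gene content is copied from the
#' track identically for homologous copies; activity is initially unset
#' (every monomer inactive at the physiological temperature, `T_eff = 1`).
#'
#' @param kar a `karyotype`.
#' @param track a `gene_track` covering every chromosome of `kar` along its
#'   full length.
#' @return A `monomer_table` data frame with columns `id` (0-based global
#'   id), `chrom`, `copy` (0-based), `chain_index` (0-based index along the
#'   chromosome), `gene_content`, `activity_class`, `T_eff`.
#' @export
build_monomer_table <- function(kar, track) {
  pieces <- lapply(seq_len(nrow(kar)), function(i) {
    ch <- kar$name[i]
    sub <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(sub) != kar$length_mb[i]) {
      stop(sprintf("track length for %s (%d bins) does not match karyotype (%d Mb)",
                   ch, nrow(sub), kar$length_mb[i]))
    }
    sub <- sub[order(sub$start), , drop = FALSE]
    do.call(rbind, lapply(seq_len(kar$copies[i]) - 1L, function(cp) {
      data.frame(chrom = ch, copy = cp,
                 chain_index = seq_len(nrow(sub)) - 1L,
                 gene_content = sub$gene_content,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  out <- cbind(id = seq_len(nrow(out)) - 1L, out)
  out$activity_class <- "inactive"
  out$T_eff <- 1
  rownames(out) <- NULL
  class(out) <- c("monomer_table", "data.frame")
  out
}

#' Assign activity classes and effective temperatures
#'
#' In the inhomogeneous mode the monomers with the largest gene content are
#' flagged active and given effective temperature `T_a` (in units of the
#' physiological temperature); exactly `round(active_fraction * N)` monomers
#' are flagged (round half away from zero), with ties broken by gene content
#' descending then global id ascending. The homogeneous mode raises every
#' monomer to `T_a`; the equilibrium mode resets every monomer to the
#' physiological temperature.
#'
#' @param table a `monomer_table`.
#' @param mode one of "inhomogeneous", "homogeneous", "equilibrium".
#' @param active_fraction fraction of monomers flagged active (default 0.05,
#'   the top-5 percent rule).
#' @param T_a active effective temperature in units of the physiological
#'   temperature (>= 1; default 20, the scale of the free energy liberated
#'   by ATP hydrolysis in thermal units).
#' @return The table with `activity_class` and `T_eff` filled in.
#' @export
assign_activity <- function(table,
                            mode = c("inhomogeneous", "homogeneous",
                                     "equilibrium"),
                            active_fraction = 0.05, T_a = 20) {
  mode <- match.arg(mode)
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must lie in [0, 1]")
  }
  if (T_a < 1) stop("T_a must be >= 1 (in units of the physiological temperature)")
  n <- nrow(table)
  table$activity_class <- "inactive"
  table$T_eff <- 1
  if (mode == "homogeneous") {
    table$activity_class <- "active"
    table$T_eff <- T_a
  } else if (mode == "inhomogeneous") {
    n_active <- floor(active_fraction * n + 0.5)  # round half away from zero
    if (n_active > 0) {
      ord <- order(-table$gene_content, table$id)
      sel <- ord[seq_len(n_active)]
      table$activity_class[sel] <- "active"
      table$T_eff[sel] <- T_a
    }
  }
  table
}

#' Mean gene density of one chromosome
#'
#' Arithmetic mean of per-monomer gene content over all copies of the given
#' chromosome, in genes/Mb.
#'
#' @param table a `monomer_table`.
#' @param chromosome chromosome label.
#' @return Mean genes/Mb (scalar).
#' @export
chromosome_density_summary <- function(table, chromosome) {
  sel <- table$chrom == chromosome
  if (!any(sel)) stop(sprintf("unknown chromosome: %s", chromosome))
  mean(table$gene_content[sel])
}

#' @export
print.monomer_table <- function(x, ...) {
  n_act <- sum(x$activity_class == "active")
  cat(sprintf("Monomer table: %d monomers, %d chromosomes, %d active%s\n",
              nrow(x), length(unique(x$chrom)), n_act,
              if (n_act) sprintf(" (T_a = %g)", max(x$T_eff)) else ""))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Named sub-streams fanned out from one top-level seed, so genome synthesis,
# loop drawing, initial placement and the dynamics noise use decoupled
# reproducible streams.
sub_seed <- function(seed, stream = c("genome", "loops", "init", "dynamics")) {
  stream <- match.arg(stream)
  off <- c(genome = 101L, loops = 211L, init = 307L, dynamics = 401L)[[stream]]
  as.integer((as.double(seed) * 7919 + off) %% 2147483629)
}
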