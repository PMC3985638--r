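#' Random loop presets
#'
#' The three looping probabilities studied with the full 6098-monomer
#' system, calibrated so the expected loop count reproduces the realized
#' counts of 424 (low), 712 (mid) and 1404 (high) loops per configuration.
#'
#' @return Named numeric vector with elements `low`, `mid`, `high`.
#' @export
loop_presets <- function() {
  c(low = 424 / 6098, mid = 712 / 6098, high = 1404 / 6098)
}

#' Generate permanent random intra-chromosomal loops
#'
#' Random loop model: each monomer independently becomes a loop-initiating
#' anchor with probability `p_loop` and is paired with a distinct partner
#' drawn uniformly from its own chain (same chromosome and copy). Loops are
#' permanent once formed: duplicate pairs are dropped, anchors on chains of
#' length one are skipped, and the loop springs are
#' `loop_k_multiplier * k_bond` stiff. Expected loop count is approximately
#' `N * p_loop`.
#'
#' @param table a `monomer_table`.
#' @param p_loop per-monomer anchor probability in [0, 1], or a preset name
#'   ("low", "mid", "high").
#' @param ff a `force_field` (supplies the loop spring constant).
#' @param seed integer RNG seed; the same seed reproduces the same loops.
#' @return A `loop_set` data frame with columns `i`, `j` (0-based monomer
#'   ids, `i < j`, both on the same chain) and `k_spring`.
#' @export
generate_loops <- function(table, p_loop, ff = force_field(), seed = 1L) {
  if (is.character(p_loop)) {
    p_loop <- loop_presets()[[match.arg(p_loop, names(loop_presets()))]]
  }
  if (p_loop < 0 || p_loop > 1) stop("p_loop must lie in [0, 1]")
  n <- nrow(table)
  chain <- paste(table$chrom, table$copy, sep = "\r")
  k_spring <- ff$loop_k_multiplier * ff$k_bond
  members <- split(seq_len(n), chain)
  withr_seed(seed, {
    anchors <- which(stats::runif(n) < p_loop)
    pairs <- matrix(integer(0), 0, 2)
    if (length(anchors)) {
      part <- vapply(anchors, function(a) {
        mates <- members[[chain[a]]]
        mates <- mates[mates != a]
        if (!length(mates)) return(NA_integer_)  # chain of length 1
        mates[sample.int(length(mates), 1L)]
      }, integer(1))
      keep <- !is.na(part)
      pairs <- cbind(pmin(anchors[keep], part[keep]),
                     pmax(anchors[keep], part[keep]))
      pairs <- unique(pairs)
    }
    out <- data.frame(i = table$id[pairs[, 1]], j = table$id[pairs[, 2]],
                      k_spring = rep(k_spring, nrow(pairs)))
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("loop_set", "data.frame")
    out
  })
}

#' Write / read a loop set
#'
#' Loop sets are serialized as plain CSV (`i`, `j`, `k_spring`) next to the
#' trajectory; they are also reproducible from (seed, preset).
#'
#' @param loops a `loop_set`.
#' @param path file path.
#' @return `write_loops`: `path` invisibly; `read_loops`: a `loop_set`.
#' @export
write_loops <- function(loops, path) {
  utils::write.csv(as.data.frame(loops), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_loops
#' @export
read_loops <- function(path) {
  out <- utils::read.csv(path, colClasses = c("integer", "integer",
                                              "numeric"))
  class(out) <- c("loop_set", "data.frame")
  out
}
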