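#' Alignment chains
#'
#' An alignment chain is an ordered set of co-linear, non-overlapping
#' ungapped blocks mapping query (haplotype/contig) coordinates onto
#' reference coordinates. All coordinates are 0-based and half-open;
#' blocks are sorted in both coordinate systems and share one strand.
#' Chains drive assembly-to-reference variant calling and depth liftover.
#'
#' @param blocks data frame with integer columns `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end`.
#' @param strand `"+"` or `"-"` (query strand relative to the reference).
#' @param ref_len,qry_len total sequence lengths.
#' @return an `aln_chain` object.
#' @export
aln_chain <- function(blocks, strand = "+", ref_len = NA_integer_,
                      qry_len = NA_integer_) {
  stopifnot(all(c("ref_start", "ref_end", "qry_start", "qry_end") %in%
                  names(blocks)))
  blocks <- blocks[order(blocks$ref_start), , drop = FALSE]
  rownames(blocks) <- NULL
  if (nrow(blocks) > 1) {
    if (any(blocks$ref_start[-1] < blocks$ref_end[-nrow(blocks)]) ||
        any(blocks$qry_start[-1] < blocks$qry_end[-nrow(blocks)]))
      stop("chain blocks must be non-overlapping and co-linear")
  }
  if (any(blocks$ref_end - blocks$ref_start !=
            blocks$qry_end - blocks$qry_start))
    stop("chain blocks must be ungapped (equal ref and qry spans)")
  structure(blocks, class = c("aln_chain", "data.frame"),
            strand = strand, ref_len = as.integer(ref_len),
            qry_len = as.integer(qry_len))
}

#' Lift positions through an alignment chain
#'
#' Maps 0-based positions from one coordinate system of a chain to the
#' other. Positions falling between blocks (inside an insertion or
#' deletion) map to `NA`.
#'
#' @param chain an [aln_chain()].
#' @param pos integer vector of 0-based positions.
#' @return integer vector of lifted positions (`NA` where unmapped).
#' @export
chain_ref_to_qry <- function(chain, pos) {
  i <- findInterval(pos, chain$ref_start)
  ok <- i >= 1 & !is.na(pos)
  ok[ok] <- pos[ok] < chain$ref_end[i[ok]]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- chain$qry_start[i[ok]] + (pos[ok] - chain$ref_start[i[ok]])
  out
}

#' @rdname chain_ref_to_qry
#' @export
chain_qry_to_ref <- function(chain, pos) {
  o <- order(chain$qry_start)
  qs <- chain$qry_start[o]; qe <- chain$qry_end[o]; rs <- chain$ref_start[o]
  i <- findInterval(pos, qs)
  ok <- i >= 1 & !is.na(pos)
  ok[ok] <- pos[ok] < qe[i[ok]]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- rs[i[ok]] + (pos[ok] - qs[i[ok]])
  out
}

#' Project a query interval onto the reference through a chain
#'
#' Returns the smallest reference interval containing the images of all
#' aligned positions of the query interval, or `NA`s when no block
#' overlaps it (e.g. a read drawn entirely from an inserted segment).
#'
#' @param chain an [aln_chain()].
#' @param start,end 0-based half-open query interval.
#' @return list with `ref_start` and `ref_end` (possibly `NA`).
#' @export
chain_project_interval <- function(chain, start, end) {
  hit <- chain$qry_end > start & chain$qry_start < end
  if (!any(hit)) return(list(ref_start = NA_integer_, ref_end = NA_integer_))
  b <- chain[hit, , drop = FALSE]
  first <- b[1, ]; last <- b[nrow(b), ]
  rs <- first$ref_start + max(0L, start - first$qry_start)
  re <- last$ref_end - max(0L, last$qry_end - end)
  list(ref_start = as.integer(rs), ref_end = as.integer(re))
}

#' Alignment blocks of a chain, with per-block identity
#'
#' Flattens a chain into the block table used by the contiguity metrics
#' ([nga50()], [duplication_ratio()], [coverage_fraction()]). When the two
#' sequences are supplied, per-block identity is computed by direct
#' comparison.
#'
#' @param chain an [aln_chain()].
#' @param qry,ref optional sequences for identity computation.
#' @return data frame of blocks with `ref_start`, `ref_end`, `qry_start`,
#'   `qry_end`, `length`, `identity`.
#' @export
chain_to_blocks <- function(chain, qry = NULL, ref = NULL) {
  b <- as.data.frame(chain)
  b$length <- b$ref_end - b$ref_start
  b$identity <- NA_real_
  if (!is.null(qry) && !is.null(ref)) {
    for (i in seq_len(nrow(b))) {
      r <- substr(ref, b$ref_start[i] + 1, b$ref_end[i])
      q <- substr(qry, b$qry_start[i] + 1, b$qry_end[i])
      n <- nchar(r)
      mm <- sum(utf8ToInt(r) != utf8ToInt(q))
      b$identity[i] <- if (n > 0) 1 - mm / n else NA_real_
    }
  }
  b
}

#' @export
print.aln_chain <- function(x, ...) {
  cat(sprintf("aln_chain: %d block(s), strand %s, ref span %d-%d\n",
              nrow(x), attr(x, "strand"),
              if (nrow(x)) min(x$ref_start) else NA,
              if (nrow(x)) max(x$ref_end) else NA))
  print(as.data.frame(x), ...)
  invisible(x)
}
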