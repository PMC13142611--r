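#' Fraction of a target segment covered by a CNV call
#'
#' Computes the overlap between one raw CNV call interval and one breakpoint
#' segment, as a fraction of the segment length (half-open arithmetic). The
#' fraction is of the TARGET segment, not of the call; calls on another
#' chromosome contribute 0.
#'
#' @param call A list or one-row data.frame with `chrom`, `start`, `end`.
#' @param segment A [cnv_segment()].
#' @return Numeric fraction in \[0, 1\].
#' @export
segment_overlap_fraction <- function(call, segment) {
  if (as.character(call$chrom) != segment$chrom) return(0)
  ov <- max(0, min(call$end, segment$end) - max(call$start, segment$start))
  ov / (segment$end - segment$start)
}

# Per-segment coverage fractions for one sample's merged calls of one state.
# merged: matrix from .merge_intervals (already chromosome-filtered).
# overlap_mode "target": fraction of the segment covered (the default rule);
# "call": denominator is the total merged call length (the bedtools -f
# fraction-of-call alternative).
.coverage_fractions <- function(merged, locus, overlap_mode = "target") {
  vapply(locus$segments, function(seg) {
    ov <- .overlap_length(merged, seg$start, seg$end)
    denom <- switch(overlap_mode,
                    target = seg$end - seg$start,
                    call = sum(merged[, 2L] - merged[, 1L]),
                    stop("unknown overlap_mode: ", overlap_mode))
    if (denom <= 0) 0 else ov / denom
  }, numeric(1))
}

# Decide span positivity for one state given per-segment coverage fractions.
.span_positive <- function(fractions, locus, span, min_fraction) {
  seg_names <- vapply(locus$segments, `[[`, character(1), "name")
  f <- fractions[match(span$segments, seg_names)]
  g <- fractions[match(span$flanking, seg_names)]
  all(f >= min_fraction) && (length(g) == 0L || all(g < min_fraction))
}

#' Assign a locus-level CNV genotype for one sample
#'
#' Implements the union genotyping rule. For each state (DEL, DUP) the
#' sample's same-state calls are merged (union of intervals, so fragmented
#' calls are not penalized); the span is state-positive iff every segment of
#' the span has merged coverage fraction >= `min_fraction` and no flanking
#' segment of the span reaches `min_fraction`. Exactly one positive state
#' gives that call; neither gives `REF`; both give `NO_CALL` (conservative,
#' conflicts are reported via the `"conflict"` attribute).
#'
#' @param calls data.frame of raw calls for ONE sample: columns `chrom`,
#'   `start`, `end`, `state` (`"DEL"`/`"DUP"`). May be empty.
#' @param locus A [segmented_locus()].
#' @param span Span name defined in `locus`.
#' @param min_fraction Per-segment coverage threshold (default 0.5).
#' @param overlap_mode `"target"` (fraction of the segment; default) or
#'   `"call"` (fraction of the merged call length).
#' @return One of `"DEL"`, `"DUP"`, `"REF"`, `"NO_CALL"`.
#' @export
assign_genotype <- function(calls, locus, span, min_fraction = 0.5,
                            overlap_mode = c("target", "call")) {
  overlap_mode <- match.arg(overlap_mode)
  sp <- .locus_span(locus, span)
  pos <- vapply(c("DEL", "DUP"), function(state) {
    sub <- calls[calls$state == state & as.character(calls$chrom) == locus$chrom, ,
                 drop = FALSE]
    merged <- .merge_intervals(sub$start, sub$end)
    fr <- .coverage_fractions(merged, locus, overlap_mode)
    .span_positive(fr, locus, sp, min_fraction)
  }, logical(1))
  if (pos[["DEL"]] && pos[["DUP"]]) {
    structure("NO_CALL", conflict = TRUE)
  } else if (pos[["DEL"]]) "DEL" else if (pos[["DUP"]]) "DUP" else "REF"
}

#' Genotype a full callset against a catalog
#'
#' Applies [assign_genotype()] to every sample x allele span. Samples with
#' no call near a locus are `REF` there. The output is invariant to the
#' order of input rows; DEL/DUP conflicts at a span are reported via a
#' message and returned as `NO_CALL` rows flagged in the `"conflicts"`
#' attribute, never silently dropped.
#'
#' @param calls data.frame of raw calls: `chrom`, `start`, `end`,
#'   `sample_id`, `state` (optionally `quality`, carried but unused).
#' @param catalog A `cnv_catalog`.
#' @param samples Optional character vector of all sample ids (so samples
#'   without calls appear as `REF`). Defaults to the ids seen in `calls`.
#' @param min_fraction,overlap_mode Passed to [assign_genotype()].
#' @return Long-format data.frame: `sample_id`, `locus_id`, `span`, `call`.
#' @export
genotype_matrix <- function(calls, catalog, samples = NULL,
                            min_fraction = 0.5,
                            overlap_mode = c("target", "call")) {
  overlap_mode <- match.arg(overlap_mode)
  if (is.null(samples)) samples <- unique(as.character(calls$sample_id))
  samples <- sort(unique(as.character(samples)))
  conflicts <- list()
  out <- list()
  for (locus in catalog) {
    bounds <- .locus_bounds(locus)
    near <- calls[as.character(calls$chrom) == locus$chrom &
                    calls$end > bounds[1L] & calls$start < bounds[2L], ,
                  drop = FALSE]
    span_names <- vapply(locus$spans, `[[`, character(1), "name")
    # samples with no call near the locus are REF at every span
    geno <- matrix("REF", nrow = length(samples), ncol = length(span_names),
                   dimnames = list(samples, span_names))
    for (sid in intersect(unique(as.character(near$sample_id)), samples)) {
      sub <- near[near$sample_id == sid, , drop = FALSE]
      for (sp in span_names) {
        g <- assign_genotype(sub, locus, sp, min_fraction, overlap_mode)
        if (isTRUE(attr(g, "conflict"))) {
          conflicts[[length(conflicts) + 1L]] <-
            data.frame(sample_id = sid, locus_id = locus$locus_id, span = sp,
                       stringsAsFactors = FALSE)
        }
        geno[sid, sp] <- as.character(g)
      }
    }
    out[[locus$locus_id]] <- data.frame(
      sample_id = rep(samples, times = length(span_names)),
      locus_id = locus$locus_id,
      span = rep(span_names, each = length(samples)),
      call = as.vector(geno),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(conflicts)) {
    conflicts <- do.call(rbind, conflicts)
    message(nrow(conflicts),
            " sample-span combination(s) with conflicting DEL and DUP",
            " positivity set to NO_CALL")
    attr(res, "conflicts") <- conflicts
  }
  res
}

#' Reshape long genotypes to one column per allele span
#'
#' Convenience for joining genotypes onto a cohort table: produces a
#' data.frame with `sample_id` and one column per span, named
#' `"<locus_id>|<span>"` (or just the span name when it equals the locus id).
#'
#' @param genotypes Long-format output of [genotype_matrix()].
#' @return Wide data.frame keyed by `sample_id`.
#' @export
genotypes_wide <- function(genotypes) {
  key <- ifelse(genotypes$span == genotypes$locus_id, genotypes$span,
                paste(genotypes$locus_id, genotypes$span, sep = "|"))
  samples <- sort(unique(genotypes$sample_id))
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (k in unique(key)) {
    sub <- genotypes[key == k, ]
    out[[k]] <- sub$call[match(samples, sub$sample_id)]
  }
  out
}

#' @rdname genotypes_wide
#' @param locus_id,span Components of a span key.
#' @export
span_key <- function(locus_id, span) {
  ifelse(span == locus_id, span, paste(locus_id, span, sep = "|"))
}
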