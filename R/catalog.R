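#' Construct a breakpoint segment
#'
#' A segment is one modular sub-interval of a recurrent-CNV hotspot,
#' delimited by segmental-duplication clusters (e.g. the "A-B" interval of
#' 22q11.2). Coordinates are 0-based half-open throughout the package.
#'
#' @param name Short label, e.g. `"A-B"`.
#' @param chrom Chromosome label.
#' @param start,end Base-pair coordinates, 0-based half-open; `start < end`.
#' @return A list of class `cnv_segment`.
#' @export
cnv_segment <- function(name, chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end) {
    stop("malformed segment coordinates for '", name, "': start=", start,
         ", end=", end)
  }
  structure(list(name = as.character(name), chrom = as.character(chrom),
                 start = start, end = end),
            class = "cnv_segment")
}

#' Construct a segmented recurrent-CNV locus
#'
#' A locus holds the ordered, non-overlapping breakpoint segments of one
#' hotspot together with the allele spans that are genotyped over it. Each
#' span is a contiguous run of segments; a span may name flanking segments
#' whose involvement disqualifies the span genotype (the union rule used at
#' multi-breakpoint regions such as 22q11.2, where an A-D deletion requires
#' coverage of A-B, B-C and C-D and no CNV over D-E through G-H).
#'
#' @param locus_id Locus identifier.
#' @param chrom Chromosome label.
#' @param segments List of [cnv_segment()] objects, ordered by start.
#' @param spans List of spans; each a list with `name`, `segments`
#'   (character vector of segment names forming a contiguous run) and
#'   optional `flanking` (character vector of guarding segment names).
#' @return A list of class `segmented_locus`.
#' @export
segmented_locus <- function(locus_id, chrom, segments, spans) {
  seg_names <- vapply(segments, function(s) s$name, character(1))
  if (anyDuplicated(seg_names)) stop("duplicate segment names in ", locus_id)
  starts <- vapply(segments, function(s) s$start, numeric(1))
  ends <- vapply(segments, function(s) s$end, numeric(1))
  o <- order(starts)
  segments <- segments[o]
  starts <- starts[o]
  ends <- ends[o]
  seg_names <- seg_names[o]
  if (length(segments) > 1L && any(ends[-length(ends)] > starts[-1L])) {
    stop("overlapping segments within locus ", locus_id)
  }
  spans <- lapply(spans, function(sp) {
    sp$flanking <- if (is.null(sp$flanking)) character(0) else as.character(sp$flanking)
    sp$segments <- as.character(sp$segments)
    unknown <- setdiff(c(sp$segments, sp$flanking), seg_names)
    if (length(unknown)) {
      stop("span '", sp$name, "' of locus ", locus_id,
           " names unknown segment(s): ", paste(unknown, collapse = ", "))
    }
    idx <- match(sp$segments, seg_names)
    if (length(idx) > 1L && !all(diff(sort(idx)) == 1L)) {
      stop("span '", sp$name, "' of locus ", locus_id,
           " is not a contiguous run of segments")
    }
    if (length(intersect(sp$segments, sp$flanking))) {
      stop("span '", sp$name, "' of locus ", locus_id,
           " lists a segment as its own flanking guard")
    }
    sp
  })
  structure(list(locus_id = as.character(locus_id), chrom = as.character(chrom),
                 segments = segments, spans = spans),
            class = "segmented_locus")
}

#' @export
print.segmented_locus <- function(x, ...) {
  cat("<segmented_locus> ", x$locus_id, " (", x$chrom, "): ",
      length(x$segments), " segment(s), ", length(x$spans), " span(s)\n",
      sep = "")
  invisible(x)
}

.locus_bounds <- function(locus) {
  c(min(vapply(locus$segments, `[[`, numeric(1), "start")),
    max(vapply(locus$segments, `[[`, numeric(1), "end")))
}

.locus_segment <- function(locus, name) {
  for (s in locus$segments) if (s$name == name) return(s)
  stop("unknown segment '", name, "' in locus ", locus$locus_id)
}

.locus_span <- function(locus, name) {
  for (sp in locus$spans) if (sp$name == name) return(sp)
  stop("unknown span '", name, "' in locus ", locus$locus_id)
}

#' Load a recurrent-locus catalog
#'
#' Reads a JSON catalog of segmented recurrent-CNV loci. The file holds a
#' `loci` array; each locus has `locus_id`, `chrom`, a `segments` array of
#' `{name, start, end}` and a `spans` array of
#' `{name, segments, flanking}`. Coordinates are 0-based half-open unless
#' `one_based = TRUE`, in which case 1-based inclusive input is converted
#' on read (start - 1).
#'
#' @param path Path to the catalog JSON file.
#' @param one_based Logical; set `TRUE` for 1-based inclusive coordinates.
#' @return A list of [segmented_locus()] objects, class `cnv_catalog`.
#' @seealso [default_catalog()], [enumerate_alleles()]
#' @export
load_catalog <- function(path, one_based = FALSE) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$loci)) stop("catalog file has no 'loci' entry: ", path)
  loci <- lapply(raw$loci, function(lc) {
    segs <- lapply(lc$segments, function(s) {
      start <- as.numeric(s$start)
      if (one_based) start <- start - 1
      cnv_segment(s$name, lc$chrom, start, as.numeric(s$end))
    })
    spans <- lapply(lc$spans, function(sp) {
      list(name = sp$name,
           segments = unlist(sp$segments),
           flanking = if (is.null(sp$flanking)) character(0) else unlist(sp$flanking))
    })
    segmented_locus(lc$locus_id, lc$chrom, segs, spans)
  })
  names(loci) <- vapply(loci, `[[`, character(1), "locus_id")
  structure(loci, class = "cnv_catalog")
}

#' The packaged synthetic recurrent-locus catalog
#'
#' Returns the catalog shipped with the package: 41 single-breakpoint
#' hotspots plus one eight-breakpoint segmented locus modelled on the
#' 22q11.2 A-H architecture, for a total of 47 testable hotspot spans and
#' 94 deletion/duplication alleles. Locus names and positions are realistic
#' but synthetic: the file is a stand-in built for this package, not the
#' clinical locus list used in any published study.
#'
#' @return A `cnv_catalog` object.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "catalog_synthetic.json",
                           package = "cnvdose", mustWork = TRUE))
}

#' Enumerate testable CNV alleles in a catalog
#'
#' Each (locus, span) pair yields one deletion and one duplication allele.
#' The enumeration is deterministic: loci in catalog order, spans in locus
#' order, DEL before DUP.
#'
#' @param catalog A `cnv_catalog`.
#' @return A data.frame with columns `locus_id`, `span`, `allele`.
#' @export
enumerate_alleles <- function(catalog) {
  rows <- list()
  for (locus in catalog) {
    for (sp in locus$spans) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = locus$locus_id, span = sp$name,
        allele = c("DEL", "DUP"), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cnv_catalog <- function(x, ...) {
  alleles <- enumerate_alleles(x)
  cat("<cnv_catalog> ", length(x), " loci, ",
      nrow(alleles) / 2L, " hotspot spans, ", nrow(alleles), " alleles\n",
      sep = "")
  invisible(x)
}
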