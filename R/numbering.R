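#' Helix / loop annotation for Ballesteros-Weinstein numbering
#'
#' Class A GPCR residues are conventionally labelled \code{h.50} at the
#' most conserved position of helix h, with neighbours numbered by offset
#' (so the conserved DRY motif at the cytoplasmic end of TM3 reads
#' 3.49-3.51). ICL2, between TM3 and TM4, uses segment number 34 with the
#' same offset rule. Anchors are user-supplied per receptor; no sequence
#' motif inference is attempted.
#'
#' @param segments data.frame with columns \code{segment} (e.g. "TM3",
#'   "ICL2"), \code{start}, \code{end}, \code{anchor} (the residue carrying
#'   label x.50), residue numbers chain-local
#' @return validated data.frame of class \code{"helix_annotation"} with a
#'   derived \code{seg_num} column
#' @export
helix_annotation <- function(segments) {
  stopifnot(is.data.frame(segments))
  required <- c("segment", "start", "end", "anchor")
  if (!all(required %in% names(segments))) {
    stop("helix_annotation(): need columns ",
         paste(required, collapse = ", "))
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$anchor < segments$start |
            segments$anchor > segments$end)) {
    stop("helix_annotation(): anchor outside its residue range")
  }
  if (any(segments$start > segments$end)) {
    stop("helix_annotation(): start > end")
  }
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)])) {
    stop("helix_annotation(): overlapping segments")
  }
  seg_num <- ifelse(grepl("^TM[1-7]$", segments$segment),
                    sub("^TM", "", segments$segment),
                    ifelse(segments$segment == "ICL2", "34",
                           NA_character_))
  if (anyNA(seg_num)) {
    # allow numeric segment labels given directly
    direct <- grepl("^[0-9]+$", segments$segment)
    seg_num[is.na(seg_num) & direct] <- segments$segment[is.na(seg_num) & direct]
    if (anyNA(seg_num)) {
      stop("helix_annotation(): unrecognised segment label(s): ",
           paste(unique(segments$segment[is.na(seg_num)]), collapse = ", "))
    }
  }
  segments$seg_num <- seg_num
  rownames(segments) <- NULL
  class(segments) <- c("helix_annotation", "data.frame")
  segments
}

#' Read per-chain helix annotations from YAML
#'
#' Expected layout: a mapping from chain id to a list of
#' \code{\{segment, start, end, anchor\}} entries.
#'
#' @param path YAML file
#' @return named list of \code{\link{helix_annotation}} objects per chain
#' @export
read_annotation_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(chain) {
    helix_annotation(do.call(rbind, lapply(chain, as.data.frame)))
  })
}

#' Ballesteros-Weinstein label for a residue
#'
#' A residue in segment s with anchor a is labelled
#' \code{<s>.<50 + res_seq - a>}; residues outside all annotated segments
#' get \code{NA}.
#'
#' @param res_seq integer residue number(s)
#' @param ann a \code{\link{helix_annotation}}
#' @return character vector of labels (or \code{NA})
#' @export
bw_label <- function(res_seq, ann) {
  stopifnot(inherits(ann, "helix_annotation"))
  vapply(res_seq, function(r) {
    hit <- which(ann$start <= r & ann$end >= r)
    if (length(hit) == 0L) return(NA_character_)
    sprintf("%s.%d", ann$seg_num[hit[1L]], 50L + r - ann$anchor[hit[1L]])
  }, character(1L))
}

#' Invert a Ballesteros-Weinstein label back to a residue number
#' @param label label such as "3.50"
#' @param ann a \code{\link{helix_annotation}}
#' @return integer residue number (NA when the segment is not annotated)
#' @export
bw_residue <- function(label, ann) {
  stopifnot(inherits(ann, "helix_annotation"))
  vapply(label, function(l) {
    parts <- strsplit(l, ".", fixed = TRUE)[[1L]]
    hit <- which(ann$seg_num == parts[1L])
    if (length(hit) == 0L) return(NA_integer_)
    ann$anchor[hit[1L]] + as.integer(parts[2L]) - 50L
  }, integer(1L), USE.NAMES = FALSE)
}

#' Annotate an interaction occupancy table with BW labels
#'
#' Adds \code{bw_a}/\code{bw_b} label columns for the two end-point
#' residues and attaches a per-segment contact summary (how many retained
#' interactions touch each annotated segment, e.g. to quantify ICL2
#' enrichment at the dimer interface). Unannotated residues keep blank
#' labels; no rows are dropped.
#'
#' @param tab an \code{\link{occupancy_table}} result
#' @param ann named list of \code{\link{helix_annotation}} per chain id
#' @return the table with label columns; attribute
#'   \code{"segment_summary"}: data.frame \code{segment, contacts,
#'   fraction} over retained interaction end-points
#' @export
annotate_interface <- function(tab, ann) {
  lab <- function(chain, res) {
    mapply(function(ch, r) {
      if (is.null(ann[[ch]])) return(NA_character_)
      bw_label(r, ann[[ch]])
    }, chain, res, USE.NAMES = FALSE)
  }
  tab$bw_a <- if (nrow(tab)) lab(tab$chain_a, tab$res_a) else character()
  tab$bw_b <- if (nrow(tab)) lab(tab$chain_b, tab$res_b) else character()
  ret <- tab[tab$retained, , drop = FALSE]
  seg_of <- function(bw) ifelse(is.na(bw), "unannotated",
                                sub("\\..*$", "", bw))
  segs <- c(seg_of(ret$bw_a), seg_of(ret$bw_b))
  summary <- if (length(segs)) {
    counts <- sort(table(segs), decreasing = TRUE)
    data.frame(segment = names(counts),
               contacts = as.integer(counts),
               fraction = as.numeric(counts) / length(segs))
  } else {
    data.frame(segment = character(), contacts = integer(),
               fraction = numeric())
  }
  attr(tab, "segment_summary") <- summary
  tab
}
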