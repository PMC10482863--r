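AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Validate a table of loop annotations
#'
#' Loop annotations place loop structures on a reference chain: `label` is
#' the N-terminal residue index of the loop in the chain, `start`/`end` the
#' 1-based inclusive residue span, `sequence` the amino acids of the span,
#' `prototype` the loop-prototype id and `age` the transferred time of
#' origin (nd).
#'
#' @param tab Data frame with columns `label`, `start`, `end`, `sequence`,
#'   `prototype`, `age`.
#' @return The validated data frame, ordered by position, with class
#'   `ef_annotations`.
#' @export
as_loop_annotations <- function(tab) {
  need <- c("label", "start", "end", "sequence", "prototype", "age")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stopf("loop annotations: missing column(s) %s",
          paste(missing, collapse = ", "))
  tab <- as.data.frame(tab)[, need]
  if (nrow(tab) == 0) stopf("loop annotations: empty table")
  tab$label <- as.integer(tab$label)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (anyDuplicated(tab$label)) stopf("loop annotations: labels must be unique")
  if (any(tab$end < tab$start)) stopf("loop annotations: end < start")
  if (any(tab$label != tab$start))
    stopf("loop annotations: label must equal the N-terminal residue index (start)")
  if (any(nchar(tab$sequence) != tab$end - tab$start + 1))
    stopf("loop annotations: sequence length must match the residue span")
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")),
                tab$sequence)
  if (any(bad))
    stopf("loop annotations: non-amino-acid characters in sequence(s) of loop(s) %s",
          paste(tab$label[bad], collapse = ", "))
  for (p in unique(tab$prototype)) parse_prototype_id(p)
  if (anyNA(tab$age) || any(tab$age < 0 | tab$age > 1))
    stopf("loop annotations: ages must lie in [0, 1]")
  tab <- tab[order(tab$start), ]
  if (nrow(tab) > 1 && any(tab$start[-1] <= tab$end[-nrow(tab)]))
    stopf("loop annotations: residue spans overlap")
  rownames(tab) <- NULL
  structure(tab, class = c("ef_annotations", "data.frame"))
}

#' Read loop annotations from a TSV file
#'
#' @param path Tab-separated file with the columns of
#'   [as_loop_annotations()].
#' @return An `ef_annotations` data frame.
#' @export
read_loop_annotations <- function(path) {
  as_loop_annotations(read_tsv_table(path))
}

#' Build time-ordered growing molecular intermediates
#'
#' Stitches loop sequences together in order of their time of origin: the
#' intermediate at each time event contains every loop whose age does not
#' exceed the event, with members concatenated in positional (N- to
#' C-terminal) order. The first intermediate is the most primordial loop
#' (or loops, for age ties); the last contains all loops. Only the loop
#' regions are stitched; inter-loop linker residues are excluded.
#'
#' @param annotations An `ef_annotations` table (or coercible data frame).
#' @return Data frame of class `ef_intermediates`: `step`, `age`,
#'   `loop_sequence` (pipe-joined labels, ascending), `amino_sequence`,
#'   `n_loops`, plus a `members` attribute (list of label vectors).
#' @examples
#' ann <- generate_toy_annotations(4, seed = 1)
#' build_intermediates(ann)
#' @export
build_intermediates <- function(annotations) {
  ann <- as_loop_annotations(annotations)
  events <- sort(unique(ann$age))
  members <- lapply(events, function(e) ann$label[ann$age <= e])
  rows <- lapply(seq_along(events), function(i) {
    sel <- ann[ann$label %in% members[[i]], ]
    sel <- sel[order(sel$start), ]
    data.frame(step = i, age = events[i],
               loop_sequence = paste(sel$label, collapse = "|"),
               amino_sequence = paste(sel$sequence, collapse = ""),
               n_loops = nrow(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("ef_intermediates", "data.frame"),
            members = lapply(members, sort))
}

#' @export
print.ef_intermediates <- function(x, ...) {
  cat(sprintf("<ef_intermediates> %d growing molecules:\n", nrow(x)))
  cat(paste0("  ", x$loop_sequence, " (nd = ", format(x$age), ")\n"), sep = "")
  invisible(x)
}

#' Loop replacement variants of an intermediate
#'
#' Systematically replaces the loop at one slot of a loop sequence by each
#' candidate loop, keeping only substitutions that preserve the strictly
#' ascending positional order (the stitched chain must remain N- to
#' C-terminal). Used for reshuffling experiments probing the sensitivity of
#' fold convergence to loop composition.
#'
#' @param base A loop sequence: pipe-joined label string (e.g.
#'   `"34|80|186|213"`), an integer label vector, or a one-row
#'   `ef_intermediates`.
#' @param slot 1-based index of the loop to replace.
#' @param candidates Candidate loops: an `ef_annotations` table or an integer
#'   vector of labels.
#' @param annotations Optional `ef_annotations` covering the base loops (and
#'   candidates) so variant amino sequences can be stitched.
#' @return Data frame `loop_sequence`, `slot`, `replacement`,
#'   `amino_sequence` (NA without annotations), with attribute `rejected`
#'   (data frame `label`, `reason`).
#' @export
reshuffle_variants <- function(base, slot, candidates, annotations = NULL) {
  labels <- base_labels(base)
  if (!is_count(slot) || slot < 1 || slot > length(labels))
    stopf("slot must index one of the %d loops", length(labels))
  cand <- if (is.data.frame(candidates)) as.integer(candidates$label)
          else as.integer(candidates)
  cand_ann <- if (is.data.frame(candidates)) as_loop_annotations(candidates)
              else NULL
  lower <- if (slot > 1) labels[slot - 1] else -Inf
  upper <- if (slot < length(labels)) labels[slot + 1] else Inf
  ok <- cand > lower & cand < upper & !cand %in% labels[-slot]
  rejected <- data.frame(
    label = cand[!ok],
    reason = rep("breaks ascending positional order", sum(!ok)),
    stringsAsFactors = FALSE)
  kept <- cand[ok]
  if (length(kept) == 0)
    warnf("no admissible candidate for slot %d of %s", slot,
          paste(labels, collapse = "|"))
  ann <- annotations
  if (!is.null(ann)) {
    ann <- as.data.frame(as_loop_annotations(ann))
    if (!is.null(cand_ann)) {
      extra <- as.data.frame(cand_ann)
      extra <- extra[!extra$label %in% ann$label, , drop = FALSE]
      ann <- as_loop_annotations(rbind(ann, extra))
    }
  } else if (!is.null(cand_ann)) {
    ann <- cand_ann
  }
  rows <- lapply(kept, function(cl) {
    newlab <- labels; newlab[slot] <- cl
    amino <- NA_character_
    if (!is.null(ann) && all(newlab %in% ann$label)) {
      sel <- ann[match(newlab, ann$label), ]
      amino <- paste(sel$sequence[order(sel$start)], collapse = "")
    }
    data.frame(loop_sequence = paste(newlab, collapse = "|"),
               slot = slot, replacement = cl, amino_sequence = amino,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(loop_sequence = character(), slot = integer(),
               replacement = integer(), amino_sequence = character())
  structure(out, rejected = rejected)
}

base_labels <- function(base) {
  if (inherits(base, "ef_intermediates")) {
    if (nrow(base) != 1) stopf("base must be a single intermediate")
    base <- base$loop_sequence
  }
  if (is.character(base)) {
    labels <- as.integer(strsplit(base, "|", fixed = TRUE)[[1]])
  } else {
    labels <- as.integer(base)
  }
  if (anyNA(labels) || length(labels) == 0)
    stopf("base loop sequence is malformed")
  if (is.unsorted(labels, strictly = TRUE))
    stopf("base loop sequence labels must strictly ascend")
  labels
}

#' Write a series of intermediates as multi-FASTA
#'
#' One record per growing molecule; the header carries the loop sequence and
#' its age (`34|80|186|213 nd=0.184`). Sequences are validated over the
#' 20-letter amino-acid alphabet.
#'
#' @param intermediates An `ef_intermediates` data frame.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_fasta_series <- function(intermediates, path) {
  if (nrow(intermediates) == 0) stopf("empty intermediate series")
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")),
                intermediates$amino_sequence)
  if (any(bad))
    stopf("non-amino-acid characters in intermediate(s): %s",
          paste(intermediates$loop_sequence[bad], collapse = ", "))
  seqs <- Biostrings::AAStringSet(intermediates$amino_sequence)
  names(seqs) <- sprintf("%s nd=%s", intermediates$loop_sequence,
                         format(intermediates$age, trim = TRUE))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
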