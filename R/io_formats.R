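# The ten bracing codes of the DS classification: pairs of secondary
# structures flanking the aperiodic loop region (H alpha-helix, E beta-strand,
# G 3_10 helix, BN beta hairpin, BK beta link).
BRACING_CODES <- c("HH", "HE", "EH", "HG", "GH", "GG", "EG", "GE", "BN", "BK")

#' Parse a loop-prototype identifier
#'
#' Loop prototypes are named `METHOD.BRACING.LEN.CLASS.SUBCLASS`, e.g.
#' `DS.HE.3.1.1`: Density-Search clustering, helix/strand bracing structures,
#' a 3-residue aperiodic loop region, and conformation class / geometry
#' subclass ranks.
#'
#' @param s A single identifier string.
#' @return An object of class `prototype_id` with fields `method`, `bracing`,
#'   `loop_length`, `class_rank`, `subclass_rank`.
#' @examples
#' parse_prototype_id("DS.HE.3.1.1")
#' @export
parse_prototype_id <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stopf("prototype id must be a non-empty string")
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(parts) != 5L)
    stopf("malformed prototype id '%s': expected 5 dot-separated fields, got %d",
          s, length(parts))
  if (!nzchar(parts[1]))
    stopf("malformed prototype id '%s': empty method field", s)
  if (!parts[2] %in% BRACING_CODES)
    stopf("unknown bracing code '%s' in prototype id '%s'", parts[2], s)
  nums <- suppressWarnings(as.integer(parts[3:5]))
  if (anyNA(nums) || any(parts[3:5] != as.character(nums)))
    stopf("malformed prototype id '%s': non-integer length/class/subclass", s)
  if (nums[1] < 0) stopf("prototype id '%s': negative loop length", s)
  if (nums[2] < 1 || nums[3] < 1)
    stopf("prototype id '%s': class and subclass ranks must be positive", s)
  structure(list(method = parts[1], bracing = parts[2],
                 loop_length = nums[1], class_rank = nums[2],
                 subclass_rank = nums[3]),
            class = "prototype_id")
}

#' @export
format.prototype_id <- function(x, ...) {
  paste(x$method, x$bracing, x$loop_length, x$class_rank, x$subclass_rank,
        sep = ".")
}

#' @export
print.prototype_id <- function(x, ...) {
  cat("<loop prototype>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.prototype_id <- function(x, ...) format(x)

#' Parse a SCOP concise classification string (ccs)
#'
#' Fold-family domains are identified by strings like `c.37.1.12`:
#' class letter, then fold, superfamily and family numbers.
#'
#' @param s A single ccs string.
#' @return An object of class `scop_ccs` with fields `scop_class`, `fold`,
#'   `superfamily`, `family`.
#' @examples
#' parse_scop_ccs("c.2.1.2")
#' @export
parse_scop_ccs <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stopf("ccs must be a non-empty string")
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stopf("malformed ccs '%s': expected class.fold.superfamily.family", s)
  if (!grepl("^[A-Za-z]$", parts[1]))
    stopf("malformed ccs '%s': class must be a single letter", s)
  nums <- suppressWarnings(as.integer(parts[2:4]))
  if (anyNA(nums) || any(parts[2:4] != as.character(nums)) || any(nums < 1))
    stopf("malformed ccs '%s': fold/superfamily/family must be positive integers", s)
  structure(list(scop_class = parts[1], fold = nums[1],
                 superfamily = nums[2], family = nums[3]),
            class = "scop_ccs")
}

#' @export
format.scop_ccs <- function(x, ...) {
  paste(x$scop_class, x$fold, x$superfamily, x$family, sep = ".")
}

#' @export
print.scop_ccs <- function(x, ...) {
  cat("<SCOP ccs>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.scop_ccs <- function(x, ...) format(x)

read_tsv_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a loop-to-domain mapping table
#'
#' Reads a tab-separated table with header columns `loop` and `domain`
#' (and optionally `evalue`), validates both identifier grammars, filters on
#' e-value, and collapses duplicate (loop, domain) pairs keeping the minimum
#' e-value.
#'
#' @param path Path to the TSV file. Lines starting with `#` are comments.
#' @param evalue_max Optional e-value threshold; records with
#'   `evalue >= evalue_max` are dropped (the reference analysis used 0.001).
#' @return A data frame of class `ef_mapping` with columns `loop`, `domain`,
#'   `evalue`, and attributes `n_read`, `n_kept`, `n_dropped_evalue`,
#'   `n_duplicates`.
#' @export
read_mapping_table <- function(path, evalue_max = NULL) {
  tab <- read_tsv_table(path)
  required <- c("loop", "domain")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stopf("mapping table %s: missing required column(s) %s", path,
          paste(missing, collapse = ", "))
  if (!"evalue" %in% names(tab)) tab$evalue <- NA_real_
  tab <- tab[, c("loop", "domain", "evalue")]
  tab$evalue <- as.numeric(tab$evalue)
  as_mapping_table(tab, evalue_max = evalue_max)
}

#' Construct a mapping table from a data frame
#'
#' Validation, e-value filtering and deduplication shared by
#' [read_mapping_table()] and the synthetic-data generator.
#'
#' @param tab Data frame with columns `loop`, `domain` and optionally
#'   `evalue`.
#' @inheritParams read_mapping_table
#' @return See [read_mapping_table()].
#' @export
as_mapping_table <- function(tab, evalue_max = NULL) {
  if (!"evalue" %in% names(tab)) tab$evalue <- NA_real_
  n_read <- nrow(tab)
  if (n_read > 0) {
    for (s in unique(tab$loop)) parse_prototype_id(s)
    for (s in unique(tab$domain)) parse_scop_ccs(s)
    if (any(!is.na(tab$evalue) & tab$evalue <= 0))
      stopf("mapping table: e-values must be positive")
  }
  n_drop <- 0L
  if (!is.null(evalue_max) && n_read > 0) {
    keep <- is.na(tab$evalue) | tab$evalue < evalue_max
    n_drop <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
  }
  n_dup <- 0L
  if (nrow(tab) > 0) {
    key <- paste(tab$loop, tab$domain, sep = "\r")
    if (anyDuplicated(key)) {
      n_dup <- sum(duplicated(key))
      conflicting <- tapply(tab$evalue, key, function(e) {
        e <- e[!is.na(e)]
        length(unique(e)) > 1
      })
      if (any(conflicting, na.rm = TRUE))
        warnf("mapping table: %d duplicate pair(s) with conflicting e-values; keeping minimum",
              sum(conflicting, na.rm = TRUE))
      ord <- order(key, tab$evalue, na.last = TRUE)
      tab <- tab[ord, , drop = FALSE]
      tab <- tab[!duplicated(key[ord]), , drop = FALSE]
    }
    tab <- tab[order(tab$loop, tab$domain), , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab, class = c("ef_mapping", "data.frame"),
            n_read = n_read, n_kept = nrow(tab),
            n_dropped_evalue = n_drop, n_duplicates = n_dup)
}

#' @export
print.ef_mapping <- function(x, ...) {
  cat(sprintf("<ef_mapping> %d records (%d loops, %d domains); read %d, dropped %d by e-value, %d duplicates\n",
              nrow(x), length(unique(x$loop)), length(unique(x$domain)),
              attr(x, "n_read"), attr(x, "n_dropped_evalue"),
              attr(x, "n_duplicates")))
  if (nrow(x) > 0) print(head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a domain chronology
#'
#' Reads a tab-separated table with columns `domain` (SCOP ccs) and `nd`
#' (relative time of origin in \[0, 1\], 0 = origin of proteins, 1 = the
#' present).
#'
#' @param path Path to the TSV file.
#' @return An object of class `ef_chronology`: a data frame (`domain`, `nd`)
#'   with attribute `events`, the sorted unique nd values.
#' @export
read_chronology <- function(path) {
  tab <- read_tsv_table(path)
  missing <- setdiff(c("domain", "nd"), names(tab))
  if (length(missing))
    stopf("chronology %s: missing required column(s) %s", path,
          paste(missing, collapse = ", "))
  as_chronology(tab[, c("domain", "nd")])
}

#' Construct a chronology from a data frame
#'
#' @param tab Data frame with columns `domain` and `nd`.
#' @return See [read_chronology()].
#' @export
as_chronology <- function(tab) {
  tab$nd <- as.numeric(tab$nd)
  if (nrow(tab) > 0) {
    for (s in unique(tab$domain)) parse_scop_ccs(s)
    if (anyNA(tab$nd) || any(tab$nd < 0 | tab$nd > 1))
      stopf("chronology: nd values must lie in [0, 1]")
    ages <- tapply(tab$nd, tab$domain, unique, simplify = FALSE)
    bad <- names(ages)[vapply(ages, length, 1L) > 1]
    if (length(bad))
      stopf("chronology: domain(s) repeated with different nd: %s",
            paste(bad, collapse = ", "))
    tab <- tab[!duplicated(tab$domain), , drop = FALSE]
    tab <- tab[order(tab$nd, tab$domain), , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab, class = c("ef_chronology", "data.frame"),
            events = sort(unique(tab$nd)))
}

#' @export
print.ef_chronology <- function(x, ...) {
  cat(sprintf("<ef_chronology> %d domains over %d time events (nd %s..%s)\n",
              nrow(x), length(attr(x, "events")),
              if (nrow(x)) format(min(x$nd)) else "-",
              if (nrow(x)) format(max(x$nd)) else "-"))
  invisible(x)
}

#' Look up domain ages
#'
#' @param chronology An `ef_chronology`.
#' @param domains Character vector of ccs strings.
#' @return Named numeric vector of nd ages.
#' @export
domain_ages <- function(chronology, domains) {
  idx <- match(domains, chronology$domain)
  if (anyNA(idx))
    stopf("domain(s) absent from chronology: %s",
          paste(unique(domains[is.na(idx)]), collapse = ", "))
  setNames(chronology$nd[idx], domains)
}

#' The default molecular clock of folds
#'
#' Linear nd-to-geological-time mapping anchored at nd = 0 (3.8 Gy ago,
#' the origin of proteins) and nd = 1 (the present, 0 Gy).
#'
#' @return An object of class `ef_clock`.
#' @export
default_clock <- function() {
  structure(list(intercept = 3.8, slope = -3.8,
                 pearson_r = NA_real_, spearman_rho = NA_real_,
                 residual_ss = 0, n_points = 2L),
            class = "ef_clock")
}

#' Fit a molecular clock from calibration points
#'
#' Least-squares linear fit of geological age (Gy) on relative age (nd),
#' with Pearson and Spearman correlation statistics attached.
#'
#' @param calibration Data frame or matrix with columns `nd` and `gy`.
#' @return An object of class `ef_clock` with fields `intercept` (Gy at
#'   nd = 0), `slope` (Gy per nd unit), `pearson_r`, `spearman_rho`,
#'   `residual_ss`.
#' @export
fit_clock <- function(calibration) {
  cal <- as.data.frame(calibration)
  if (!all(c("nd", "gy") %in% names(cal))) {
    if (ncol(cal) >= 2) names(cal)[1:2] <- c("nd", "gy")
    else stopf("calibration must have columns nd and gy")
  }
  if (nrow(cal) < 2) stopf("clock calibration needs at least 2 points")
  if (length(unique(cal$nd)) < 2)
    stopf("clock calibration needs at least 2 distinct nd values")
  fit <- lm(gy ~ nd, data = cal)
  r <- cor(cal$nd, cal$gy, method = "pearson")
  rho <- suppressWarnings(cor(cal$nd, cal$gy, method = "spearman"))
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 pearson_r = r, spearman_rho = rho,
                 residual_ss = sum(fit$residuals^2),
                 n_points = nrow(cal)),
            class = "ef_clock")
}

#' @export
print.ef_clock <- function(x, ...) {
  cat(sprintf("<ef_clock> Gy = %.4f %+.4f * nd (%d calibration points",
              x$intercept, x$slope, x$n_points))
  if (!is.na(x$pearson_r))
    cat(sprintf("; r = %.3f, rho = %.3f", x$pearson_r, x$spearman_rho))
  cat(")\n")
  invisible(x)
}

#' Convert relative age (nd) to geological time (Gy)
#'
#' @param nd Numeric vector of relative ages in \[0, 1\].
#' @param clock An `ef_clock`; defaults to the two-anchor clock
#'   (nd = 0 at 3.8 Gy, nd = 1 at 0 Gy).
#' @return Numeric vector of ages in billions of years before present.
#' @examples
#' nd_to_gy(c(0, 0.5, 1))
#' @export
nd_to_gy <- function(nd, clock = default_clock()) {
  if (anyNA(nd) || any(nd < 0 | nd > 1))
    stopf("nd values must lie in [0, 1]")
  clock$intercept + clock$slope * nd
}
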