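#' Transfer domain ages to loop prototypes
#'
#' A loop embedded in domain structures inherits its time of origin from
#' them. Two transfer schemes are supported: (1) the age of the most ancient
#' associated domain, or (2) the age of the more recent of the pair of most
#' ancient associated domains (the age at which the loop is first shared
#' between scaffolds). Under scheme 2, loops whose oldest partner sits at the
#' global minimum domain age keep their scheme-1 age: with no older donor
#' domain available, the first loop must found the first domain.
#'
#' @param mapping An `ef_mapping`.
#' @param chronology An `ef_chronology` covering every mapped domain.
#' @param scheme Age-transfer scheme, `1` or `2`.
#' @return Data frame with one row per distinct loop: `loop`, `scheme1_age`,
#'   `scheme2_age`, `age` (the requested scheme, with the scheme-2
#'   exception applied), `n_domains`, `n_distinct_ages`.
#' @export
assign_loop_ages <- function(mapping, chronology, scheme = 2) {
  if (!scheme %in% c(1, 2)) stopf("scheme must be 1 or 2")
  ages <- domain_ages(chronology, mapping$domain)
  split_ages <- split(unname(ages), mapping$loop)
  global_min <- min(chronology$nd)
  res <- lapply(names(split_ages), function(lp) {
    a <- sort(split_ages[[lp]])
    s1 <- a[1]
    s2 <- if (length(a) == 1L) a[1] else a[2]
    # exception: no older donor domain exists for loops anchored at the
    # global minimum age, so scheme 2 falls back to scheme 1 there
    if (s1 == global_min) s2 <- s1
    data.frame(loop = lp, scheme1_age = s1, scheme2_age = s2,
               n_domains = length(a), n_distinct_ages = length(unique(a)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$age <- if (scheme == 1) out$scheme1_age else out$scheme2_age
  out <- out[order(out$loop), c("loop", "scheme1_age", "scheme2_age", "age",
                                "n_domains", "n_distinct_ages")]
  rownames(out) <- NULL
  out
}

#' Classify loop prototypes as modular, contemporaneous-modular or
#' non-modular
#'
#' A prototype mapping to a single domain is non-modular (`NM`); one mapping
#' to two or more domains that all share one time of origin is
#' contemporaneous-modular (`M'`); one mapping to domains of at least two
#' distinct ages is modular (`M`).
#'
#' @inheritParams assign_loop_ages
#' @return Object of class `ef_classification`: data frame `loop`, `label`
#'   (factor with levels `M`, `M'`, `NM`), `n_domains`, `n_distinct_ages`,
#'   with a `counts` attribute.
#' @export
classify_prototypes <- function(mapping, chronology) {
  la <- assign_loop_ages(mapping, chronology, scheme = 1)
  label <- ifelse(la$n_domains == 1L, "NM",
                  ifelse(la$n_distinct_ages == 1L, "M'", "M"))
  out <- data.frame(loop = la$loop,
                    label = factor(label, levels = c("M", "M'", "NM")),
                    n_domains = la$n_domains,
                    n_distinct_ages = la$n_distinct_ages,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ef_classification", "data.frame"),
            counts = table(out$label))
}

#' @export
print.ef_classification <- function(x, ...) {
  ct <- attr(x, "counts")
  cat(sprintf("<ef_classification> %d loops: %d M, %d M', %d NM\n",
              nrow(x), ct[["M"]], ct[["M'"]], ct[["NM"]]))
  invisible(x)
}

#' Venn partition of domains by the kinds of loops they recruit
#'
#' Splits the chronology's domains into those mapping only to modular loops
#' (`M` or `M'`), only to non-modular loops, to both, and those with no
#' mapped loop at all.
#'
#' @inheritParams assign_loop_ages
#' @param classification An `ef_classification` covering every loop in
#'   `mapping`.
#' @return List of class `ef_venn` with character vectors `m_only`,
#'   `nm_only`, `both`, `unmapped`.
#' @export
venn_domains <- function(mapping, classification, chronology) {
  idx <- match(mapping$loop, classification$loop)
  if (anyNA(idx))
    stopf("classification does not cover loop(s): %s",
          paste(unique(mapping$loop[is.na(idx)]), collapse = ", "))
  is_mod <- classification$label[idx] %in% c("M", "M'")
  doms <- unique(mapping$domain)
  has_m <- doms %in% unique(mapping$domain[is_mod])
  has_nm <- doms %in% unique(mapping$domain[!is_mod])
  out <- list(m_only = sort(doms[has_m & !has_nm]),
              nm_only = sort(doms[!has_m & has_nm]),
              both = sort(doms[has_m & has_nm]),
              unmapped = sort(setdiff(chronology$domain, doms)))
  structure(out, class = "ef_venn")
}

#' @export
print.ef_venn <- function(x, ...) {
  cat(sprintf("<ef_venn> %d M-only, %d NM-only, %d both, %d unmapped domains\n",
              length(x$m_only), length(x$nm_only), length(x$both),
              length(x$unmapped)))
  invisible(x)
}
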