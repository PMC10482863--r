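#' Configuration for the synthetic loop-domain generator
#'
#' Defaults emulate the broad statistical shape of the curated loop-domain
#' dataset: roughly 72% of prototypes are non-modular, contemporaneous-
#' modular pairs are rare, and modular loops are reused preferentially in
#' proportion to how often they have already been recruited.
#'
#' @param n_domains Number of domains (one loop prototype is born with each).
#' @param n_events Number of distinct time events (<= n_domains); ages are
#'   event ranks normalized to \[0, 1\].
#' @param nm_fraction Probability that a newborn loop is non-modular.
#' @param mprime_rate Probability that a newborn loop is contemporaneous-
#'   modular (maps to two domains of the same event).
#' @param attach_exponent Preferential-reuse strength: existing modular loops
#'   are recruited with probability proportional to degree^attach_exponent.
#' @param reuse_rate Expected number of extra modular-loop recruitments per
#'   domain (Poisson).
#' @param n_blocks,p_in,p_out Planted-partition parameters passed to
#'   [generate_planted_partition()].
#' @param seed Integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_domains = 300, n_events = 50, nm_fraction = 0.72,
                         mprime_rate = 0.01, attach_exponent = 1,
                         reuse_rate = 0.5, n_blocks = 2, p_in = 0.25,
                         p_out = 0.01, seed = 1L) {
  if (!is_count(n_domains) || n_domains < 1) stopf("n_domains must be >= 1")
  if (!is_count(n_events) || n_events < 1) stopf("n_events must be >= 1")
  if (n_events > n_domains) stopf("n_events must not exceed n_domains")
  assert_prob(nm_fraction, "nm_fraction")
  assert_prob(mprime_rate, "mprime_rate")
  if (nm_fraction + mprime_rate > 1)
    stopf("nm_fraction + mprime_rate must not exceed 1")
  if (attach_exponent < 0) stopf("attach_exponent must be >= 0")
  if (reuse_rate < 0) stopf("reuse_rate must be >= 0")
  structure(list(n_domains = as.integer(n_domains),
                 n_events = as.integer(n_events),
                 nm_fraction = nm_fraction, mprime_rate = mprime_rate,
                 attach_exponent = attach_exponent, reuse_rate = reuse_rate,
                 n_blocks = n_blocks, p_in = p_in, p_out = p_out,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_domain_names <- function(n) {
  cls <- letters[1:7]
  paste0(cls[((seq_len(n) - 1) %% 7) + 1], ".",
         ((seq_len(n) - 1) %/% 7) + 1, ".1.1")
}

synth_loop_names <- function(n) {
  idx <- seq_len(n) - 1L
  paste0("DS.", BRACING_CODES[(idx %% 10) + 1], ".3.",
         (idx %/% 10) + 1, ".1")
}

#' Generate a synthetic mapping table and chronology with ground truth
#'
#' Emulates a growing timeline of domains recruiting loop prototypes. Each
#' domain appears at a time event (event ranks normalized to nd in
#' \[0, 1\]) and births one loop whose planted label is drawn at random:
#' non-modular (probability `nm_fraction`, mapped 1:1 to its domain),
#' contemporaneous-modular (`mprime_rate`, paired with a second domain of the
#' same event when one exists), or modular. Modular loops receive one
#' guaranteed strictly-younger acceptor domain plus further acceptors drawn
#' by preferential reuse: each arriving domain additionally recruits
#' Poisson(`reuse_rate`) older modular loops with probability proportional to
#' their current degree raised to `attach_exponent`. Loops born at the final
#' event (or without an available same-event partner) cannot realize their
#' drawn label and are planted non-modular; ground truth records the realized
#' labels.
#'
#' @param cfg A [synth_config()].
#' @return List with `mapping` (`ef_mapping`), `chronology`
#'   (`ef_chronology`), and `truth` (list: `labels` data frame with the
#'   planted per-loop labels, `domain_events`, `cfg`).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    nd_dom <- cfg$n_domains
    ev <- ceiling(seq_len(nd_dom) * cfg$n_events / nd_dom)
    nd_of_event <- if (cfg$n_events == 1) 0 else
      (seq_len(cfg$n_events) - 1) / (cfg$n_events - 1)
    dom <- synth_domain_names(nd_dom)
    loop <- synth_loop_names(nd_dom)

    pairs_from <- character(0); pairs_to <- character(0)
    add_pair <- function(l, d) {
      pairs_from <<- c(pairs_from, l); pairs_to <<- c(pairs_to, d)
    }
    label <- character(nd_dom)
    loop_deg <- setNames(integer(nd_dom), loop)
    mod_pool <- integer(0)      # indices of planted-M loops
    mod_event <- integer(0)     # their birth events

    for (i in seq_len(nd_dom)) {
      # preferential reuse of older modular loops by the arriving domain
      elig <- mod_pool[mod_event < ev[i]]
      n_extra <- rpois(1, cfg$reuse_rate)
      if (length(elig) > 0 && n_extra > 0) {
        n_extra <- min(n_extra, length(elig))
        w <- (loop_deg[elig] ^ cfg$attach_exponent)
        if (all(w == 0)) w <- rep(1, length(elig))
        picked <- if (length(elig) == 1) elig else
          sample(elig, n_extra, replace = FALSE, prob = w)
        for (p in picked) {
          add_pair(loop[p], dom[i])
          loop_deg[p] <- loop_deg[p] + 1L
        }
      }

      # the domain's own newborn loop
      u <- runif(1)
      add_pair(loop[i], dom[i])
      loop_deg[i] <- 1L
      if (u < cfg$nm_fraction) {
        label[i] <- "NM"
      } else if (u < cfg$nm_fraction + cfg$mprime_rate) {
        mates <- which(ev == ev[i])
        mates <- mates[mates != i]
        if (length(mates) == 0) {
          label[i] <- "NM"
        } else {
          partner <- if (length(mates) == 1) mates else sample(mates, 1)
          add_pair(loop[i], dom[partner])
          loop_deg[i] <- 2L
          label[i] <- "M'"
        }
      } else {
        younger <- which(ev > ev[i])
        if (length(younger) == 0) {
          label[i] <- "NM"
        } else {
          acceptor <- if (length(younger) == 1) younger else
            sample(younger, 1)
          add_pair(loop[i], dom[acceptor])
          loop_deg[i] <- 2L
          label[i] <- "M"
          mod_pool <- c(mod_pool, i)
          mod_event <- c(mod_event, ev[i])
        }
      }
    }

    mapping <- as_mapping_table(data.frame(
      loop = pairs_from, domain = pairs_to,
      evalue = NA_real_, stringsAsFactors = FALSE))
    chronology <- as_chronology(data.frame(
      domain = dom, nd = nd_of_event[ev], stringsAsFactors = FALSE))
    truth <- list(labels = data.frame(loop = loop, label = label,
                                      stringsAsFactors = FALSE),
                  domain_events = setNames(ev, dom), cfg = cfg)
    list(mapping = mapping, chronology = chronology, truth = truth)
  })
}

#' Seeded sample from a discrete power law
#'
#' i.i.d. draws from P(X = k) proportional to k^(-alpha), k >= xmin, with
#' zeta normalization; an oracle input for the power-law fitting statistics.
#'
#' @param alpha Exponent (> 1).
#' @param n Sample size.
#' @param seed Integer seed.
#' @param xmin Lower support bound.
#' @return Integer-valued numeric vector.
#' @export
generate_power_law_sample <- function(alpha, n, seed = 1L, xmin = 1) {
  if (!is.numeric(alpha) || alpha <= 1) stopf("alpha must exceed 1")
  if (!is_count(n) || n < 1) stopf("n must be >= 1")
  with_seed(seed, rzeta(n, alpha, xmin))
}

#' Generate toy loop annotations for stitching tests
#'
#' Non-overlapping ascending residue spans with random lengths, valid
#' amino-acid sequences, valid prototype ids and random ages (the first loop
#' is anchored at nd = 0).
#'
#' @param n_loops Number of loops (>= 1).
#' @param seed Integer seed.
#' @return An `ef_annotations` data frame.
#' @export
generate_toy_annotations <- function(n_loops, seed = 1L) {
  if (!is_count(n_loops) || n_loops < 1) stopf("n_loops must be >= 1")
  with_seed(seed, {
    len <- sample(3:8, n_loops, replace = TRUE)
    gap <- sample(1:5, n_loops, replace = TRUE)
    start <- cumsum(c(1, (len + gap)[-n_loops]))
    ages <- c(0, sort(runif(n_loops - 1)))
    as_loop_annotations(data.frame(
      label = start, start = start, end = start + len - 1,
      sequence = vapply(len, function(l)
        paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""), ""),
      prototype = synth_loop_names(n_loops),
      age = ages, stringsAsFactors = FALSE))
  })
}
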