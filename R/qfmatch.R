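# Quadratic-form cluster matching between two samples: gate candidate
# pairs by median proximity, match greedily by smallest QF dissimilarity,
# then resolve unmatched clusters by exhaustive merging into split-vs-
# missing decisions.

#' Median proximity gate
#'
#' Two clusters are comparable when their medians are no more than
#' `mult` standard deviations apart in every dimension, with the per-
#' dimension scale `max(sd_a, sd_b)`. Dimensions where both SDs are zero
#' compare medians for exact equality.
#'
#' @param a,b Subsets as produced by [make_subsets()].
#' @param mult Gate width in standard deviations.
#' @return `TRUE` when the pair passes the gate.
#' @export
median_gate <- function(a, b, mult = 4) {
  if (length(a$median) != length(b$median)) {
    stop("shape error: subsets live in different channel spaces")
  }
  s <- pmax(a$sd, b$sd)
  delta <- abs(a$median - b$median)
  all(ifelse(s == 0, delta == 0, delta <= mult * s))
}

#' Match clusters between two samples by quadratic-form dissimilarity
#'
#' Builds one shared adaptive binning over the two full samples, scores
#' every gate-passing cluster pair by QF dissimilarity, accepts the
#' globally smallest scores one-to-one (greedy), and resolves the leftover
#' clusters by exhaustive merging: an unmatched cluster whose merger with
#' neighbouring clusters of its own sample lowers the score against some
#' counterpart is recorded as part of a cluster split; otherwise it is a
#' missing population.
#'
#' @param a,b Each either an [epp()] fit, or a [sic_events()]/matrix (then
#'   supply `labels_a`/`labels_b`).
#' @param labels_a,labels_b Integer cluster labels when `a`/`b` are event
#'   tables.
#' @param channels Channels to match on (names or indices); default all.
#' @param cfg A [sic_config()] (`gate_mult`, `merge_cap`).
#' @return An object of class `qfmatch` with `matches` (one row per
#'   alignment: A labels, B labels, score, kind `match`/`split`), `missing`,
#'   `scores` (candidate table; `NA` = gated out), and the binning summary.
#' @export
#' @examples
#' \donttest{
#' specs <- canonical_pair_specs()
#' sim <- simulate_pair(specs$spec_a, specs$spec_b, seed = 1)
#' m <- qfmatch(sim$events_a, sim$events_b,
#'              labels_a = sim$labels_a, labels_b = sim$labels_b)
#' m
#' }
qfmatch <- function(a, b, labels_a = NULL, labels_b = NULL,
                    channels = NULL, cfg = sic_config()) {
  if (inherits(a, "epp") || inherits(b, "epp")) {
    stop("pass the event tables alongside epp fits via qfmatch_epp()")
  }
  va <- event_values(a); vb <- event_values(b)
  if (is.null(labels_a) || is.null(labels_b)) {
    stop("cluster labels are required for both samples")
  }
  if (length(labels_a) != nrow(va) || length(labels_b) != nrow(vb)) {
    stop("label/event count mismatch: labels must have one entry per event")
  }
  dims <- if (is.null(channels)) {
    seq_len(ncol(va))
  } else if (is.numeric(channels)) {
    as.integer(channels)
  } else {
    idx <- match(channels, colnames(va))
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(channels[is.na(idx)], collapse = ", "))
    idx
  }

  subsets_a <- make_subsets(va, labels_a, dims = dims)
  subsets_b <- make_subsets(vb, labels_b, dims = dims)
  if (length(subsets_a) == 0L || length(subsets_b) == 0L) {
    stop("empty input: both samples need at least one cluster")
  }

  binning <- adaptive_bin(va, vb, dims = dims)
  if (binning$B == 1L) {
    warning("degenerate binning (B = 1): QF scores are all zero; ",
            "matching falls back to median-distance ordering")
  }
  sim <- bin_similarity(binning)
  fa <- lapply(subsets_a, function(s) bin_cluster(binning, va, s$indices))
  fb <- lapply(subsets_b, function(s) bin_cluster(binning, vb, s$indices))

  na <- length(subsets_a); nb <- length(subsets_b)
  scores <- matrix(NA_real_, na, nb,
                   dimnames = list(
                     vapply(subsets_a, `[[`, integer(1), "label"),
                     vapply(subsets_b, `[[`, integer(1), "label")))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (median_gate(subsets_a[[i]], subsets_b[[j]], mult = cfg$gate_mult)) {
        scores[i, j] <- qf_distance(fa[[i]], fb[[j]], sim)
        if (binning$B == 1L) {
          scores[i, j] <- sqrt(sum((subsets_a[[i]]$median -
                                      subsets_b[[j]]$median)^2))
        }
      }
    }
  }

  # Greedy one-to-one: repeatedly accept the globally smallest remaining
  # score; ties break on the lower (A label, B label) pair.
  avail <- scores
  pairs <- list()
  while (any(is.finite(avail))) {
    k <- which(avail == min(avail, na.rm = TRUE), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    pairs[[length(pairs) + 1L]] <- list(i = k[1], j = k[2],
                                        score = avail[k[1], k[2]])
    avail[k[1], ] <- NA_real_
    avail[, k[2]] <- NA_real_
  }
  matched_a <- vapply(pairs, `[[`, numeric(1), "i")
  matched_b <- vapply(pairs, `[[`, numeric(1), "j")
  cand_a <- setdiff(seq_len(na), matched_a)
  cand_b <- setdiff(seq_len(nb), matched_b)

  matches <- lapply(pairs, function(p) {
    list(a_labels = subsets_a[[p$i]]$label, b_labels = subsets_b[[p$j]]$label,
         score = p$score, kind = "match")
  })
  missing <- list()

  # --- merging resolution ------------------------------------------------
  resolve_side <- function(cands, subsets_s, f_s, subsets_o, f_o,
                           values_s, sample_s, partner_in_s) {
    # cands: indices (into subsets_s) of unmatched clusters in sample S.
    # For each, try merging with clusters of S against counterparts in the
    # other sample O; partner_in_s maps O index -> the S index currently
    # matched to it (NA if none). A counterpart's matched partner is part
    # of every merge group tried against it, so each cluster stays
    # accounted for exactly once.
    consumed <- integer(0)
    for (ci in cands) {
      if (ci %in% consumed) next
      best <- NULL
      for (oi in seq_along(subsets_o)) {
        s0 <- score_lookup(sample_s, ci, oi)
        if (!is.finite(s0)) next  # gated out: no basis for a merge claim
        # Counterparts already involved in a split stay settled.
        o_label <- subsets_o[[oi]]$label
        o_in_split <- any(vapply(matches, function(m) {
          m$kind == "split" && (if (sample_s == "B") o_label %in% m$a_labels
                                else o_label %in% m$b_labels)
        }, logical(1)))
        if (o_in_split) next
        mandatory <- partner_in_s[[oi]]
        if (!is.na(mandatory) &&
            !median_gate(subsets_s[[mandatory]], subsets_o[[oi]],
                         mult = cfg$gate_mult)) next
        optional <- setdiff(cands, c(ci, consumed))
        optional <- optional[vapply(optional, function(p) {
          median_gate(subsets_s[[p]], subsets_o[[oi]], mult = cfg$gate_mult)
        }, logical(1))]
        if (is.na(mandatory) && length(optional) == 0L) next
        if (2^length(optional) > cfg$merge_cap) {
          dm <- vapply(optional, function(p) {
            sqrt(sum((subsets_s[[p]]$median - subsets_o[[oi]]$median)^2))
          }, numeric(1))
          optional <- optional[order(dm)][seq_len(floor(log2(cfg$merge_cap)))]
        }
        codes <- if (is.na(mandatory)) {
          seq_len(2^length(optional) - 1L)  # need at least one extra member
        } else {
          seq_len(2^length(optional)) - 1L  # the partner alone suffices
        }
        for (code in codes) {
          grp <- optional[bitwAnd(code, 2^(seq_along(optional) - 1L)) > 0]
          members <- c(ci, if (!is.na(mandatory)) mandatory, grp)
          idx <- unlist(lapply(subsets_s[members], `[[`, "indices"))
          fm <- bin_cluster(binning, values_s, idx)
          sc <- qf_distance(fm, f_o[[oi]], sim)
          if (sc < s0 && (is.null(best) || sc < best$score)) {
            best <- list(oi = oi, members = members, score = sc)
          }
        }
      }
      if (is.null(best)) {
        missing[[length(missing) + 1L]] <<- list(
          sample = sample_s,
          label = subsets_s[[ci]]$label)
      } else {
        consumed <- c(consumed, setdiff(best$members, ci))
        s_labels <- sort(vapply(subsets_s[best$members], `[[`, integer(1),
                                "label"))
        o_label <- subsets_o[[best$oi]]$label
        # Replace any plain match of the counterpart by the split record.
        drop <- vapply(matches, function(m) {
          if (sample_s == "B") {
            identical(m$a_labels, o_label) && m$kind == "match"
          } else {
            identical(m$b_labels, o_label) && m$kind == "match"
          }
        }, logical(1))
        matches <<- matches[!drop]
        matches[[length(matches) + 1L]] <<- if (sample_s == "B") {
          list(a_labels = o_label, b_labels = s_labels,
               score = best$score, kind = "split")
        } else {
          list(a_labels = s_labels, b_labels = o_label,
               score = best$score, kind = "split")
        }
        consumed <- c(consumed, ci)
      }
    }
    consumed
  }
  score_lookup <- function(sample_s, si, oi) {
    if (sample_s == "B") scores[oi, si] else scores[si, oi]
  }
  # For each counterpart cluster, the index of its matched partner in the
  # opposite sample (NA when unmatched).
  b_partner_of_a <- lapply(seq_len(na), function(i) {
    j <- matched_b[matched_a == i]
    if (length(j)) as.integer(j) else NA_integer_
  })
  a_partner_of_b <- lapply(seq_len(nb), function(j) {
    i <- matched_a[matched_b == j]
    if (length(i)) as.integer(i) else NA_integer_
  })
  resolve_side(cand_b, subsets_b, fb, subsets_a, fa, vb, "B", b_partner_of_a)
  # Clusters already absorbed into a split are no longer candidates.
  accounted_a <- unlist(lapply(matches, `[[`, "a_labels"))
  cand_a <- cand_a[!(vapply(subsets_a[cand_a], `[[`, integer(1), "label")
                     %in% accounted_a)]
  resolve_side(cand_a, subsets_a, fa, subsets_b, fb, va, "A", a_partner_of_b)

  structure(
    list(matches = matches, missing = missing, scores = scores,
         pre_merge = lapply(pairs, function(p) {
           list(a_label = subsets_a[[p$i]]$label,
                b_label = subsets_b[[p$j]]$label, score = p$score)
         }),
         candidates = list(
           A = vapply(subsets_a[cand_a], `[[`, integer(1), "label"),
           B = vapply(subsets_b[cand_b], `[[`, integer(1), "label")),
         subsets_a = subsets_a, subsets_b = subsets_b,
         binning = binning[c("L", "B", "n_small", "n_merged")],
         dims = dims, config = cfg),
    class = "qfmatch"
  )
}

#' Match two EPP fits
#'
#' Convenience wrapper pairing each fit with its event table.
#'
#' @param fit_a,fit_b [epp()] objects.
#' @param events_a,events_b The event tables the fits were computed from.
#' @param ... Passed to [qfmatch()].
#' @return A [qfmatch()] object.
#' @export
qfmatch_epp <- function(fit_a, events_a, fit_b, events_b, ...) {
  stopifnot(inherits(fit_a, "epp"), inherits(fit_b, "epp"))
  qfmatch(events_a, events_b, labels_a = fit_a$labels,
          labels_b = fit_b$labels, ...)
}

#' @export
print.qfmatch <- function(x, ...) {
  cat(sprintf("QFMatch: %d x %d clusters, binning B = %d (L = %d)\n",
              nrow(x$scores), ncol(x$scores), x$binning$B, x$binning$L))
  for (m in x$matches) {
    cat(sprintf("  A{%s} <-> B{%s}  score = %.6g  [%s]\n",
                paste(m$a_labels, collapse = ","),
                paste(m$b_labels, collapse = ","), m$score, m$kind))
  }
  for (m in x$missing) {
    cat(sprintf("  %s{%s}  missing (no counterpart)\n", m$sample, m$label))
  }
  invisible(x)
}

#' @export
summary.qfmatch <- function(object, ...) {
  data.frame(
    a_labels = vapply(object$matches, function(m)
      paste(m$a_labels, collapse = "+"), character(1)),
    b_labels = vapply(object$matches, function(m)
      paste(m$b_labels, collapse = "+"), character(1)),
    score = vapply(object$matches, `[[`, numeric(1), "score"),
    kind = vapply(object$matches, `[[`, character(1), "kind")
  )
}

#' Write a match report CSV
#'
#' One row per alignment: A labels, B labels (joined with `+`), QF score
#' and kind (`match`/`split`), followed by rows for missing clusters.
#'
#' @param x A [qfmatch()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match_csv <- function(x, path) {
  stopifnot(inherits(x, "qfmatch"))
  df <- summary(x)
  if (length(x$missing) > 0L) {
    df <- rbind(df, data.frame(
      a_labels = vapply(x$missing, function(m)
        if (m$sample == "A") paste(m$label) else "", character(1)),
      b_labels = vapply(x$missing, function(m)
        if (m$sample == "B") paste(m$label) else "", character(1)),
      score = NA_real_, kind = "missing"
    ))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
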