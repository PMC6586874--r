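# Shared fixtures and oracles for the test suite.

# Best label agreement over one-to-one assignments of found clusters to
# ground-truth groups (exhaustive over assignments; K is always small here).
label_agreement <- function(found, truth) {
  K <- max(found); G <- max(truth)
  tab <- table(factor(found, levels = seq_len(K)),
               factor(truth, levels = seq_len(G)))
  best <- 0
  assign_next <- function(k, used, acc) {
    if (k > K) { best <<- max(best, acc); return(invisible(NULL)) }
    for (g in setdiff(seq_len(G), used)) {
      assign_next(k + 1L, c(used, g), acc + tab[k, g])
    }
    assign_next(k + 1L, used, acc)  # leave cluster k unassigned
    invisible(NULL)
  }
  assign_next(1L, integer(0), 0)
  best / length(found)
}

# The canonical paired fixture at a fixed seed, computed once per test run.
canonical_sim <- local({
  cache <- new.env()
  function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      specs <- canonical_pair_specs()
      cache[[key]] <- simulate_pair(specs$spec_a, specs$spec_b, seed = seed)
    }
    cache[[key]]
  }
})

# A small, quickly clusterable 3D mixture: three well-separated components.
small_mixture <- function(n_per = 1500L, seed = 42L) {
  spec <- mixture_spec(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                       sds = 1, counts = rep(n_per, 3L))
  sim <- simulate_pair(spec, spec, seed = seed)
  list(events = sim$events_a, labels = sim$labels_a)
}

# Match-set summary of a qfmatch result: sorted "A{..}~B{..}:kind" strings.
match_signature <- function(m) {
  sort(vapply(m$matches, function(x) {
    sprintf("A{%s}~B{%s}:%s", paste(sort(x$a_labels), collapse = ","),
            paste(sort(x$b_labels), collapse = ","), x$kind)
  }, character(1)))
}
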