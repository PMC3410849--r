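test_that("histogram bin conventions: half-open bins, closed or open top", {
  fb <- fps_bins()
  expect_equal(histogram_prob(rep(1, 5), fb),
               c(rep(0, 9), 1)) # 1.0 lands in the closed last bin
  expect_equal(histogram_prob(c(0.05, 0.95), fb),
               c(0.5, rep(0, 8), 0.5))
  expect_equal(histogram_prob(c(0.1), fb), c(0, 1, rep(0, 8)))
  lb <- lrms_bins()
  expect_equal(length(histogram_prob(0, lb)), 10)
  expect_equal(histogram_prob(c(0.5, 9.5, 42), lb)[10], 2 / 3) # open top
  expect_null(histogram_prob(numeric(0), fb))
  set.seed(500)
  p <- histogram_prob(runif(1000), fb)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(abs(p - 0.1) < 0.03))
})

# a small three-level world expressed directly as keys + planted similarities
planted_world <- function() {
  dimers <- list()
  for (f in 1:2) for (p in 1:2) for (s in 1:2) for (r in 1:2) {
    id <- sprintf("f%dp%ds%dr%d", f, p, s, r)
    dimers[[id]] <- key_dimer(id, paste0("asm_", id),
                              c(sprintf("sa%d%d%d", f, p, s),
                                sprintf("sb%d%d%d", f, p, s)),
                              c(sprintf("pa%d%d", f, p),
                                sprintf("pb%d%d", f, p)),
                              c(sprintf("fa%d", f), sprintf("fb%d", f)))
  }
  h <- build_hierarchy(dimers)
  recs <- list()
  ids <- names(dimers)
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    a <- dimers[[ids[j]]]
    b <- dimers[[ids[i]]]
    if (ppiface:::fam_key_of(a) != ppiface:::fam_key_of(b)) next
    # planted: same sequence pair -> 0.95; same protein pair -> 0.55;
    # interologs -> 0.15
    v <- if (identical(a$seq_pair, b$seq_pair)) 0.95
    else if (identical(a$prot_pair, b$prot_pair)) 0.55 else 0.15
    recs[[length(recs) + 1]] <-
      key_record(a$id, b$id, v, ppiface:::seq_key_of(a),
                 ppiface:::seq_key_of(b), ppiface:::prot_key_of(a),
                 ppiface:::prot_key_of(b), ppiface:::fam_key_of(a),
                 asmA = a$assembly_id, asmB = b$assembly_id)
  }
  list(dimers = dimers, hierarchy = h, records = do.call(rbind, recs))
}

test_that("D-SameSeq averages only within-sequence comparisons", {
  pw <- planted_world()
  d <- d_sameseq(pw$records, pw$hierarchy)
  expect_equal(sum(d$p), 1, tolerance = 1e-9)
  expect_equal(d$p[10], 1) # all within-seq comparisons planted at 0.95
  expect_equal(d$n_top_groups, 2)
})

test_that("D-SameProt uses cross-child comparisons only", {
  pw <- planted_world()
  d <- d_sameprot(pw$records, pw$hierarchy)
  expect_equal(sum(d$p), 1, tolerance = 1e-9)
  expect_equal(d$p[6], 1) # only the 0.55 cross-variant values
})

test_that("D-Interolog crosses protein pairs and matches exhaustive oracle", {
  pw <- planted_world()
  d <- d_interolog(pw$records, pw$hierarchy,
                   caps = list(max_prot_pairs = Inf, max_seq_pairs = Inf))
  expect_equal(sum(d$p), 1, tolerance = 1e-9)
  expect_equal(d$p[2], 1) # all cross-protein values planted at 0.15
  # oracle: exhaustive enumeration over every (prot pair, seq pair) combo
  mv <- pw$records[pw$records$prot_keyA != pw$records$prot_keyB, ]
  fams <- unique(mv$fam_key)
  fam_hists <- lapply(fams, function(fk) {
    sub <- mv[mv$fam_key == fk, ]
    prots <- sort(unique(c(sub$prot_keyA, sub$prot_keyB)))
    pair_hists <- list()
    for (i in seq_along(prots)) for (j in seq_len(i - 1)) {
      sel <- sub[(sub$prot_keyA == prots[i] & sub$prot_keyB == prots[j]) |
                   (sub$prot_keyA == prots[j] & sub$prot_keyB == prots[i]), ]
      combos <- unique(data.frame(a = pmin(sel$seq_keyA, sel$seq_keyB),
                                  b = pmax(sel$seq_keyA, sel$seq_keyB)))
      ch <- lapply(seq_len(nrow(combos)), function(k) {
        v <- sel$fps[(pmin(sel$seq_keyA, sel$seq_keyB) == combos$a[k]) &
                       (pmax(sel$seq_keyA, sel$seq_keyB) == combos$b[k])]
        histogram_prob(v, fps_bins())
      })
      pair_hists[[length(pair_hists) + 1]] <-
        colMeans(do.call(rbind, ch))
    }
    colMeans(do.call(rbind, pair_hists))
  })
  oracle <- colMeans(do.call(rbind, fam_hists))
  expect_equal(unname(d$p), unname(oracle), tolerance = 1e-12)
  # caps that do not bind change nothing
  d50 <- d_interolog(pw$records, pw$hierarchy,
                     caps = list(max_prot_pairs = 50, max_seq_pairs = 50),
                     seed = 7)
  expect_equal(d50$p, d$p)
})

test_that("groups are weighted equally regardless of size", {
  # one group with 100 comparisons in the top bin, one with a single
  # comparison in the first bin -> equal weights
  dimers <- c(lapply(1:101, function(k) {
    key_dimer(paste0("a", k), paste0("A", k), c("s1", "s2"), c("p1", "p2"),
              c("f1", "f2"))
  }), lapply(1:2, function(k) {
    key_dimer(paste0("b", k), paste0("B", k), c("t1", "t2"), c("q1", "q2"),
              c("g1", "g2"))
  }))
  h <- build_hierarchy(dimers)
  recs <- rbind(
    do.call(rbind, lapply(1:100, function(k) {
      key_record(paste0("a", k), paste0("a", k + 1), 0.95, "s1\rs2",
                 "s1\rs2", "p1|p2", "p1|p2", "f1|f2")
    })),
    key_record("b1", "b2", 0.05, "t1\rt2", "t1\rt2", "q1|q2", "q1|q2",
               "g1|g2"))
  d <- d_sameseq(recs, h)
  expect_equal(unname(d$p), c(0.5, rep(0, 8), 0.5))
})

test_that("duplicating an Interolog group leaves all distributions unchanged", {
  pw <- planted_world()
  # clone family 1 wholesale under new keys
  clones <- lapply(Filter(function(d) d$fam_pair[1] == "fa1", pw$dimers),
                   function(d) {
                     key_dimer(paste0(d$id, "_dup"),
                               paste0(d$assembly_id, "_dup"),
                               paste0(d$seq_pair, "_dup"),
                               paste0(d$prot_pair, "_dup"),
                               paste0(d$fam_pair, "_dup"))
                   })
  rec_dup <- pw$records[pw$records$fam_key == "fa1|fb1", ]
  rec_dup$dimerA <- paste0(rec_dup$dimerA, "_dup")
  rec_dup$dimerB <- paste0(rec_dup$dimerB, "_dup")
  for (cl in c("seq_keyA", "seq_keyB", "prot_keyA", "prot_keyB", "fam_key"))
    rec_dup[[cl]] <- paste0(rec_dup[[cl]], "_dup")
  h2 <- build_hierarchy(c(pw$dimers, clones))
  r2 <- rbind(pw$records, rec_dup)
  for (fn in list(d_sameseq, d_sameprot)) {
    expect_equal(fn(r2, h2)$p, fn(pw$records, pw$hierarchy)$p,
                 tolerance = 1e-12)
  }
  caps <- list(max_prot_pairs = Inf, max_seq_pairs = Inf)
  expect_equal(d_interolog(r2, h2, caps = caps)$p,
               d_interolog(pw$records, pw$hierarchy, caps = caps)$p,
               tolerance = 1e-12)
})

test_that("bootstrap SE: zero for identical groups, closed form for two", {
  pw <- planted_world()
  d <- d_sameseq(pw$records, pw$hierarchy)
  d <- bootstrap_se(d, n_boot = 200, seed = 3)
  expect_equal(d$se, rep(0, 10)) # both group distributions identical
  # two maximally different groups: SE per bin = |p1-p2| / (2*sqrt(2))
  gp <- rbind(g1 = c(1, rep(0, 9)), g2 = c(rep(0, 9), 1))
  d2 <- ppiface:::new_distribution(fps_bins(), gp, "SameSeq", "fps", 2)
  d2 <- bootstrap_se(d2, n_boot = 4000, seed = 5)
  expect_equal(d2$se[1], 1 / (2 * sqrt(2)), tolerance = 0.05)
  expect_equal(d2$se[10], 1 / (2 * sqrt(2)), tolerance = 0.05)
  # stability: doubling n_boot moves SE by < 10%
  d3 <- bootstrap_se(d2, n_boot = 8000, seed = 5)
  expect_true(all(abs(d3$se - d2$se) / pmax(d2$se, 0.01) < 0.1))
})

test_that("cumulative mass sums whole bins and rejects off-edge thresholds", {
  gp <- rbind(g = rep(0.1, 10))
  d <- ppiface:::new_distribution(fps_bins(), gp, "SameSeq", "fps", 10)
  expect_equal(cumulative_mass(d, 0.5), 0.5)
  expect_equal(cumulative_mass(d, 0.5, "above"), 0.5)
  expect_equal(cumulative_mass(d, 0), 0)
  expect_error(cumulative_mass(d, 0.55), "bin edge")
  # direct count oracle on a planted world
  pw <- planted_world()
  di <- d_interolog(pw$records, pw$hierarchy,
                    caps = list(max_prot_pairs = Inf, max_seq_pairs = Inf))
  expect_equal(cumulative_mass(di, 0.5), 1) # all interolog values at 0.15
})
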