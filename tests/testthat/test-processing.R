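# Cleavage scoring backends and the processing-mutation call.

test_that("a zero-weight model scores logistic(0) = 0.5 everywhere", {
  m <- toy_cleavage_model(c(A = 0))
  p <- score_cleavage("ACDEFGHIKL", m)
  expect_equal(p$prob, rep(0.5, 10))
  expect_true(all(p$prob >= 0 & p$prob <= 1))
})

test_that("scores equal hand-computed logistic sums on a toy peptide", {
  # offsets 0 and +1; position i scores w0[aa_i] + w1[aa_{i+1}] + bias
  m <- toy_cleavage_model(c(A = 1, C = -2, D = 0.5), bias = 0.3,
                          offsets = c(0L, 1L),
                          extra = list("1" = c(A = 0.2, C = -0.4, D = 0.1)))
  p <- score_cleavage("ACD", m)
  lg <- function(x) 1 / (1 + exp(-x))
  expect_equal(p$prob, c(lg(0.3 + 1 + (-0.4)),    # A, next C
                         lg(0.3 - 2 + 0.1),       # C, next D
                         lg(0.3 + 0.5)))          # D, no next
})

test_that("unknown residues error by default and can be zero-weighted", {
  m <- toy_cleavage_model(c(A = 1))
  expect_error(score_cleavage("AXA", m), "non-standard")
  expect_warning(p <- score_cleavage("AXA", m, on_unknown = "zero"),
                 "zero weight")
  expect_equal(length(p$prob), 3L)
})

test_that("external score tables parse, validate residues and clip scores", {
  ctx <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIK"  # 29 residues
  tab <- data.frame(position = 1:29, residue = strsplit(ctx, "")[[1]],
                    score = seq(0.01, 0.99, length.out = 29))
  f <- tempfile()
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- parse_external_cleavage(f, ctx)
  expect_equal(length(prof$prob), 29L)
  expect_equal(prof$backend_id, "parsed_external")
  expect_equal(prof$prob, tab$score)

  bad <- tab; bad$residue[10] <- "W"
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_external_cleavage(f, ctx), "mismatch at position 10")

  clip <- tab; clip$score[1] <- 1.2
  write.table(clip, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(prof2 <- parse_external_cleavage(f, ctx), "clipped")
  expect_equal(prof2$prob[1], 1.0)

  short <- tab[-5, ]
  write.table(short, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_external_cleavage(f, ctx), "positions")
})

test_that("the 50% difference rule is applied at the epitope C-terminus", {
  mk <- function(probs) structure(list(context = strrep("A", length(probs)),
                                       prob = probs, backend_id = "x"),
                                  class = "cleavage_profile")
  # identical profiles: never a processing call
  same <- call_processing_mutation(mk(rep(0.7, 10)), mk(rep(0.7, 10)),
                                   epitope_start = 2, epitope_len = 5)
  expect_equal(same$delta, 0)
  expect_false(same$altered)
  # 0.90 vs 0.30 at the C-terminal site: delta 0.60 >= 0.50 -> altered
  wt <- rep(0.5, 10); wt[6] <- 0.90
  mu <- rep(0.5, 10); mu[6] <- 0.30
  hit <- call_processing_mutation(mk(wt), mk(mu), 2, 5)
  expect_equal(hit$delta, 0.60)
  expect_true(hit$altered)
  # 0.60 vs 0.25: delta 0.35 < 0.50 -> not altered
  wt[6] <- 0.60; mu[6] <- 0.25
  miss <- call_processing_mutation(mk(wt), mk(mu), 2, 5)
  expect_equal(miss$delta, 0.35)
  expect_false(miss$altered)
  # site policy "all" picks up off-site differences the default ignores
  wt2 <- rep(0.1, 10); mu2 <- rep(0.1, 10); mu2[1] <- 0.9
  expect_false(call_processing_mutation(mk(wt2), mk(mu2), 2, 5)$altered)
  expect_true(call_processing_mutation(mk(wt2), mk(mu2), 2, 5,
                                       sites = "all")$altered)
  expect_error(call_processing_mutation(mk(wt2), mk(rep(0.1, 9)), 2, 5),
               "length")
})

test_that("the verdict is symmetric and monotone in the threshold", {
  set.seed(33)
  mk <- function(probs) structure(list(context = strrep("A", length(probs)),
                                       prob = probs, backend_id = "x"),
                                  class = "cleavage_profile")
  for (i in 1:50) {
    a <- mk(runif(12)); b <- mk(runif(12))
    th <- runif(1)
    f <- call_processing_mutation(a, b, 3, 6, threshold = th)
    r <- call_processing_mutation(b, a, 3, 6, threshold = th)
    expect_identical(f$altered, r$altered)
    expect_equal(f$delta, r$delta)
    # raising the threshold never creates a call
    f_hi <- call_processing_mutation(a, b, 3, 6, threshold = min(1, th + 0.2))
    expect_true(!f_hi$altered || f$altered)
  }
})

test_that("scoring is deterministic and backends are exchangeable", {
  set.seed(9)
  prot <- random_peptide(60)
  mut <- data.frame(variant_id = "v1", transcript_id = "TX", gene = "G",
                    protein_position = 30L,
                    wildtype_aa = substr(prot, 30, 30),
                    mutant_aa = if (substr(prot, 30, 30) == "G") "W" else "G",
                    stringsAsFactors = FALSE)
  ep <- build_epitope_space(mut, list(TX = prot))
  model <- default_cleavage_model()
  r1 <- call_processing(ep, model)
  r2 <- call_processing(ep, model)
  expect_identical(r1, r2)

  # external backend: tables written from the internal model's profiles
  # parse back to identical profiles, hence identical processing calls
  dir <- tempfile(); dir.create(dir)
  external <- function(ctx) {
    prof <- score_cleavage(ctx, model)
    f <- file.path(dir, paste0(substr(ctx, 1, 12), nchar(ctx), ".tsv"))
    write.table(data.frame(position = seq_len(nchar(ctx)),
                           residue = strsplit(ctx, "")[[1]],
                           score = prof$prob),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    parse_external_cleavage(f, ctx)
  }
  r3 <- call_processing(ep, external)
  expect_equal(r3$mutations$is_processing, r1$mutations$is_processing)
  expect_equal(r3$epitopes$delta, r1$epitopes$delta, tolerance = 1e-12)
})

test_that("mutation-level calls OR over windows and count altered epitopes", {
  # a cross-class substitution (strong L -> weak P) must be called,
  # a within-class one (L -> I) must not
  prot <- paste0(strrep("A", 20), "L", strrep("A", 20))  # L at 21
  pos <- 21L
  mk_mut <- function(mut_aa, vid) data.frame(
    variant_id = vid, transcript_id = "TX", gene = "G",
    protein_position = pos, wildtype_aa = "L", mutant_aa = mut_aa,
    stringsAsFactors = FALSE)
  ep <- build_epitope_space(rbind(mk_mut("P", "cross"), mk_mut("I", "same")),
                            list(TX = prot))
  res <- call_processing(ep)
  calls <- res$mutations
  expect_true(calls$is_processing[calls$variant_id == "cross"])
  expect_false(calls$is_processing[calls$variant_id == "same"])
  expect_gte(calls$n_altered_epitopes[calls$variant_id == "cross"], 1L)
  expect_equal(calls$max_abs_delta[calls$variant_id == "same"], 0)
})

test_that("cleavage models round-trip through their text format", {
  m <- default_cleavage_model()
  f <- tempfile()
  write_cleavage_model(m, f)
  m2 <- read_cleavage_model(f)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$offsets, m$offsets)
  expect_equal(m2$bias, m$bias)
  expect_equal(m2$backend_id, m$backend_id)
})
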