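# Genome model: rearrangements, liftover, telomere distance, methylation rule.

test_that("reciprocal exchange matches the labeled-base oracle", {
  g <- toy_genome(genes = data.frame(chrom = "chrA", start = 7000, end = 7500,
                                     strand = "+", id = "gX"))
  res <- apply_rearrangement(
    g, rearrangement("reciprocal_translocation", donor = "chrA",
                     acceptor = "chrB", breakpoint_donor = 6000,
                     breakpoint_acceptor = 12000))
  expect_equal(res$genome$chromosomes$length, c(14000, 16000))
  expect_equal(res$genome$genes$chrom, "chrB")
  expect_equal(res$genome$genes$start, 13000)
  expect_equal(res$genome$genes$end, 13500)

  # per-base oracle: build derived id vectors explicitly
  ids <- toy_ids(c(chrA = 10000, chrB = 20000))
  derA <- c(ids$chrA[1:6000], ids$chrB[12001:20000])
  derB <- c(ids$chrB[1:12000], ids$chrA[6001:10000])
  set.seed(1)
  for (k in 1:25) {
    chrom <- sample(c("chrA", "chrB"), 1)
    len <- if (chrom == "chrA") 10000 else 20000
    s <- sample.int(len - 100, 1)
    e <- s + sample.int(100, 1)
    lv <- lift_interval(res$map, chrom, s, e)
    src <- ids[[chrom]][(s + 1):e]
    expect_equal(sum(lv$end - lv$start), e - s)
    oa <- oracle_locate(derA, src)
    ob <- oracle_locate(derB, src)
    expected <- sort(c(if (nrow(oa)) paste("chrA", oa$start, oa$end),
                       if (nrow(ob)) paste("chrB", ob$start, ob$end)))
    expect_equal(sort(paste(lv$chrom, lv$start, lv$end)), expected)
  }
})

test_that("insertional translocation conserves and moves segment length", {
  g <- toy_genome(c(chrV = 4200000, chrVI = 3500000))
  res <- apply_rearrangement(
    g, rearrangement("insertional_translocation", donor = "chrV",
                     acceptor = "chrVI", segment = c(2000000, 3880000),
                     insertion_point = 3400000))
  lens <- stats::setNames(res$genome$chromosomes$length,
                          res$genome$chromosomes$name)
  expect_equal(unname(lens["chrV"]), 4200000 - 1880000)
  expect_equal(unname(lens["chrVI"]), 3500000 + 1880000)
  expect_equal(sum(lens), 4200000 + 3500000)

  # round trip on sampled non-deleted positions
  inv <- invert_liftover(res$map)
  set.seed(2)
  for (k in 1:50) {
    chrom <- sample(c("chrV", "chrVI"), 1)
    pos <- sample.int(if (chrom == "chrV") 4200000 else 3500000, 1) - 1
    fwd <- lift_point(res$map, chrom, pos)
    back <- lift_point(inv, fwd$chrom, fwd$pos)
    expect_equal(back$chrom, chrom)
    expect_equal(back$pos, pos)
  }
})

test_that("empty rearrangement is the identity", {
  g <- toy_genome(genes = data.frame(chrom = "chrA", start = 100, end = 300,
                                     strand = "+", id = "g1"))
  res <- apply_rearrangement(
    g, rearrangement("insertion_at_locus", chrom = "chrA",
                     insertion_point = 5000))
  expect_equal(res$genome$chromosomes, g$chromosomes)
  expect_equal(res$genome$genes, g$genes)
  lv <- lift_interval(res$map, "chrA", 100, 200)
  expect_equal(lv$start, 100)
  expect_equal(lv$end, 200)
})

test_that("rearrangement validation errors", {
  g <- toy_genome()
  expect_error(apply_rearrangement(
    g, rearrangement("insertional_translocation", donor = "chrA",
                     acceptor = "chrB", segment = c(5000, 11000),
                     insertion_point = 100)), "out of bounds")
  expect_error(apply_rearrangement(
    g, rearrangement("insertional_translocation", donor = "chrA",
                     acceptor = "chrA", segment = c(2000, 6000),
                     insertion_point = 3000)), "inside the moved segment")
  circ <- apply_rearrangement(toy_genome(tel_n = 2L),
                              rearrangement("circularize", chrom = "chrA"))
  expect_error(apply_rearrangement(circ$genome,
                                   rearrangement("circularize", chrom = "chrA")),
               "already circular")
})

test_that("lift_interval handles identity, splits and deletions", {
  g <- toy_genome()
  idm <- identity_liftover(g)
  lv <- lift_interval(idm, "chrA", 100, 200)
  expect_equal(lv[, c("start", "end")], data.frame(start = 100, end = 200))
  expect_error(lift_interval(idm, "chrZ", 0, 10), "unknown chromosome")

  del <- apply_rearrangement(g, rearrangement("deletion", chrom = "chrA",
                                              segment = c(4000, 6000)))
  expect_equal(nrow(lift_interval(del$map, "chrA", 4500, 5500)), 0)
  # spanning the deletion: two pieces whose lengths sum to non-deleted bases
  lv <- lift_interval(del$map, "chrA", 3000, 7000)
  expect_equal(nrow(lv), 2)
  expect_equal(sum(lv$end - lv$start), 4000 - 2000)

  # spanning a translocation breakpoint: two target intervals, length sum
  rec <- apply_rearrangement(
    g, rearrangement("reciprocal_translocation", donor = "chrA",
                     acceptor = "chrB", breakpoint_donor = 6000,
                     breakpoint_acceptor = 12000))
  lv <- lift_interval(rec$map, "chrA", 5500, 6500)
  expect_equal(nrow(lv), 2)
  expect_equal(sum(lv$end - lv$start), 1000)
})

test_that("liftover blocks satisfy the map invariants", {
  g <- toy_genome(tel_n = 3L)
  for (r in list(
    rearrangement("reciprocal_translocation", donor = "chrA", acceptor = "chrB",
                  breakpoint_donor = 4000, breakpoint_acceptor = 15000),
    rearrangement("insertional_translocation", donor = "chrB", acceptor = "chrA",
                  segment = c(5000, 9000), insertion_point = 2000),
    rearrangement("deletion", chrom = "chrB", segment = c(100, 900)),
    rearrangement("circularize", chrom = "chrA"))) {
    m <- apply_rearrangement(g, r)$map
    b <- m$blocks
    expect_true(all(b$src_end - b$src_start == b$tgt_end - b$tgt_start))
    for (cc in unique(b$src_chrom)) {
      bb <- b[b$src_chrom == cc, ]
      bb <- bb[order(bb$src_start), ]
      if (nrow(bb) > 1)
        expect_true(all(bb$src_start[-1] >= bb$src_end[-nrow(bb)]))
    }
    for (cc in unique(b$tgt_chrom)) {
      bb <- b[b$tgt_chrom == cc, ]
      bb <- bb[order(bb$tgt_start), ]
      if (nrow(bb) > 1)
        expect_true(all(bb$tgt_start[-1] >= bb$tgt_end[-nrow(bb)]))
    }
  }
})

test_that("distance_to_repeat_capped_end follows the capped-end rule", {
  g <- annotated_genome(
    chromosomes = data.frame(name = c("c1", "c2", "c3"),
                             length = c(1e6, 5e5, 4e5),
                             circular = c(FALSE, FALSE, TRUE)),
    telomeres = data.frame(chrom = c("c1", "c1", "c2", "c2"),
                           side = c("L", "R", "L", "R"),
                           n = c(20L, 20L, 20L, 0L), nascent = FALSE))
  expect_equal(distance_to_repeat_capped_end(g, "c1", 10000), 10000)
  expect_equal(distance_to_repeat_capped_end(g, "c3", 1234), Inf)
  # only left end capped: distance from the last base is its position
  expect_equal(distance_to_repeat_capped_end(g, "c2", 5e5 - 1), 5e5 - 1)
  expect_error(distance_to_repeat_capped_end(g, "nope", 1), "unknown")
})

test_that("reevaluate_methylation implements the position rule", {
  mk <- function(domains, tel_n = 20L) annotated_genome(
    chromosomes = data.frame(name = "c1", length = 3e6, circular = FALSE),
    telomeres = data.frame(chrom = "c1", side = c("L", "R"), n = tel_n,
                           nascent = FALSE),
    domains = domains)

  # position-dependent far from any capped end: removed
  g <- mk(data.frame(chrom = "c1", start = 1.4e6, end = 1.45e6,
                     class = "position_dependent"))
  expect_equal(nrow(reevaluate_methylation(g)), 0)
  # position-independent internal: retained
  g <- mk(data.frame(chrom = "c1", start = 1.4e6, end = 1.45e6,
                     class = "position_independent"))
  expect_equal(nrow(reevaluate_methylation(g)), 1)
  # position-dependent subtelomeric: retained
  g <- mk(data.frame(chrom = "c1", start = 2000, end = 52000,
                     class = "position_dependent"))
  expect_equal(nrow(reevaluate_methylation(g)), 1)
  # zero domains, no new ends: zero domains
  g <- mk(NULL)
  expect_equal(nrow(reevaluate_methylation(g)), 0)
  # missing class tags error
  g0 <- mk(data.frame(chrom = "c1", start = 100, end = 200,
                      class = "position_dependent"))
  g0$domains$class <- NA_character_
  expect_error(reevaluate_methylation(g0), "class")
})

test_that("reevaluation is idempotent and monotone in D_tel", {
  g <- medium_genome(seed = 21)
  sc <- build_scenario("reciprocal", g, seed = 9)
  p <- sc$reeval
  once <- reevaluate_genome(sc$genome, p)
  twice <- reevaluate_genome(once, p)
  expect_equal(once$domains, twice$domains)

  # survivors at a smaller D_tel survive at a larger one
  small <- reevaluation_params(D_tel = 150e3, seed = 3)
  large <- reevaluation_params(D_tel = 300e3, seed = 3)
  base <- sc$genome
  base$telomeres$nascent <- FALSE       # isolate the survival rule
  if (nrow(base$arrays)) base$arrays$nascent <- FALSE
  d_small <- reevaluate_methylation(base, small)
  d_large <- reevaluate_methylation(base, large)
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_true(all(key(d_small) %in% key(d_large)))
})

test_that("circularization removes subtelomeric methylation, keeps internal", {
  g <- medium_genome(seed = 22)
  sc <- build_scenario("tert", g, seed = 4)
  expect_true(all(sc$genome$chromosomes$circular))
  expect_false(any(sc$truth$domains$class == "position_dependent"))
  # every internal position-independent domain survives
  pd <- g$domains[g$domains$class == "position_independent", ]
  expect_equal(sum(sc$truth$domains$class == "position_independent"), nrow(pd))
  # position-dependent domains all lost
  lost <- sc$truth$fates$fate[sc$truth$fates$class == "position_dependent"]
  expect_true(all(lost == "lost"))
})

test_that("quasiterminal translocation moves the donor telomere array", {
  g <- medium_genome(seed = 23)
  sc <- build_scenario("quasiterminal", g, seed = 5)
  r <- sc$rearrangements[[1]]
  acc <- r$acceptor; don <- r$donor
  tg <- sc$genome$telomeres
  # acceptor's new right end carries the donor's travelled array (20 units)
  expect_equal(tg$n[tg$chrom == acc & tg$side == "R"], 20L)
  # donor's broken end is capped by the acceptor's old array and is nascent
  dn <- sc$genome$telomeres[tg$chrom == don & tg$side == "R", ]
  expect_equal(dn$n, 20L)
  # a de-novo domain was nucleated at the donor's new end
  expect_equal(nrow(sc$truth$new_ends), 1)
  expect_equal(sc$truth$new_ends$chrom, don)
  expect_gte(nrow(sc$truth$de_novo), 1)
})
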