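iv_catalog <- function(starts, ends, studies,
                       classes = NULL, chrom = "chr1") {
  if (is.null(classes)) {
    classes <- ifelse(startsWith(studies, "P"), "production", "adaptation")
  }
  make_catalog(data.frame(study_id = studies, study_class = classes,
                          chrom = chrom, start = starts, end = ends,
                          stringsAsFactors = FALSE),
               tiny_layout())
}

test_that("clustering is single-linkage over pairwise overlap", {
  # complete overlap graph -> one cluster
  cl <- cluster_sweeps(iv_catalog(c(100, 120, 150), c(300, 310, 320),
                                  c("P1", "P2", "A1")))
  expect_equal(length(unique(cl$cluster_id)), 1)
  # chain A-B, B-C with A and C disjoint -> still one cluster
  cl <- cluster_sweeps(iv_catalog(c(100, 180, 260), c(200, 280, 360),
                                  c("P1", "P2", "A1")))
  expect_equal(length(unique(cl$cluster_id)), 1)
  # disjoint intervals -> singletons; adjacency does not link
  cl <- cluster_sweeps(iv_catalog(c(100, 201), c(200, 300), c("P1", "P2")))
  expect_equal(length(unique(cl$cluster_id)), 2)
  # common-intersection mode splits the chain
  cl <- cluster_sweeps(iv_catalog(c(100, 180, 260), c(200, 280, 360),
                                  c("P1", "P2", "A1")), linkage = "common")
  expect_equal(length(unique(cl$cluster_id)), 2)
})

test_that("clustering matches brute-force union-find on random catalogs", {
  lay <- tiny_layout()
  set.seed(101)
  for (rep in 1:60) {
    cat <- random_catalog(sample.int(50, 1), lay)
    got <- cluster_sweeps(cat)
    want <- oracle_cluster(cat$sweeps)
    got_part <- split(got$sweep_id, got$cluster_id)
    want_part <- split(names(want), want)
    norm <- function(p) unname(lapply(p, sort))[order(vapply(
      lapply(p, sort), `[`, character(1), 1))]
    expect_equal(norm(got_part), norm(want_part))
  }
})

test_that("every sweep lands in exactly one cluster (conservation)", {
  set.seed(77)
  cat <- random_catalog(40, tiny_layout())
  cl <- cluster_sweeps(cat)
  expect_setequal(cl$sweep_id, cat$sweeps$sweep_id)
  expect_false(anyDuplicated(cl$sweep_id) > 0)
})

test_that("CSS need >= 3 distinct studies, not 3 sweeps", {
  # three studies -> CSS
  cat <- iv_catalog(c(100, 150, 180), c(200, 300, 400),
                    c("P1", "P2", "A1"))
  css <- call_css(cluster_sweeps(cat), cat)
  expect_equal(nrow(css), 1)
  expect_equal(css$n_studies, 3)
  # flank = smallest start to largest end
  expect_equal(c(css$start, css$end), c(100, 400))
  # four sweeps from only two studies -> no CSS
  cat2 <- iv_catalog(c(100, 120, 140, 160), c(300, 310, 320, 330),
                     c("P1", "P1", "P2", "P2"))
  css2 <- call_css(cluster_sweeps(cat2), cat2)
  expect_equal(nrow(css2), 0)
  expect_equal(attr(css2, "dropped_clusters"), 1)
})

test_that("classification uses strict thresholds on class proportions", {
  classify1 <- function(studies) {
    cat <- iv_catalog(seq(100, by = 10, length.out = length(studies)),
                      seq(500, by = 10, length.out = length(studies)),
                      studies)
    css <- call_css(cluster_sweeps(cat), cat, min_studies = 1)
    classify_css(css, cat)$classification
  }
  expect_equal(classify1(c("P1", "P2", "A1")), "prodCSS")       # 0.667 > 0.6
  expect_equal(classify1(c("A1", "A2", "A3", "P1")), "adapCSS") # 0.75 > 0.7
  expect_equal(classify1(c("P1", "P2", "P3", "A1", "A2")),
               "unclassified")                                  # 0.60 exactly
  expect_equal(classify1(c("A1", "A2", "A3", "A4", "A5", "P1", "P2", "P3",
                           "P4", "P5")), "unclassified")        # 0.5 / 0.5
  # fractions sum to one
  cat <- iv_catalog(c(100, 150, 180), c(200, 300, 400),
                    c("P1", "P2", "A1"))
  css <- classify_css(call_css(cluster_sweeps(cat), cat), cat)
  expect_equal(css$prod_fraction + css$adap_fraction, 1)
  expect_error(classify_css(css, cat, prod_threshold = 1.5), "thresholds")
})

test_that("sweeps basis counts records; studies basis counts once per study", {
  # P1 contributes three sweeps, A1 and A2 one each
  cat <- iv_catalog(c(100, 110, 120, 130, 140), c(500, 510, 520, 530, 540),
                    c("P1", "P1", "P1", "A1", "A2"))
  css <- call_css(cluster_sweeps(cat), cat)
  by_study <- classify_css(css, cat, basis = "studies")
  by_sweep <- classify_css(css, cat, basis = "sweeps")
  expect_equal(by_study$prod_fraction, 1 / 3)   # P1 counts once
  expect_equal(by_sweep$prod_fraction, 3 / 5)   # every record counts
  expect_equal(by_study$classification, "unclassified")
  expect_equal(by_sweep$classification, "unclassified")  # 0.6 not > 0.6
})

test_that("raising min_studies and thresholds is monotone", {
  set.seed(202)
  cat <- random_catalog(45, tiny_layout(), n_studies = 8)
  cl <- cluster_sweeps(cat)
  n_css <- vapply(1:5, function(m) nrow(call_css(cl, cat, m)), integer(1))
  expect_true(all(diff(n_css) <= 0))
  css <- call_css(cl, cat, min_studies = 1)
  n_prod <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    sum(classify_css(css, cat, prod_threshold = th)$classification ==
          "prodCSS")
  }, integer(1))
  expect_true(all(diff(n_prod) <= 0))
})

test_that("count grid reports all four basis x threshold configurations", {
  set.seed(303)
  cat <- random_catalog(40, tiny_layout(), n_studies = 8)
  grid <- css_count_grid(cluster_sweeps(cat), cat)
  expect_equal(nrow(grid), 4)
  expect_setequal(grid$basis, c("studies", "sweeps"))
  expect_setequal(grid$adap_threshold, c(0.6, 0.7))
  # same clusters under every configuration; only classes move
  expect_equal(length(unique(grid$n_css)), 1)
  expect_true(all(grid$n_prodcss + grid$n_adapcss + grid$n_unclassified ==
                    grid$n_css))
  # loosening the adaptation threshold never loses adapCSS
  for (b in c("studies", "sweeps")) {
    g <- grid[grid$basis == b, ]
    expect_true(g$n_adapcss[g$adap_threshold == 0.6] >=
                  g$n_adapcss[g$adap_threshold == 0.7])
  }
})

test_that("CSS tables round-trip through TSV and BED", {
  cat <- iv_catalog(c(100, 150, 180, 5000, 5100, 5200),
                    c(200, 300, 400, 6000, 6100, 6300),
                    c("P1", "P2", "P3", "A1", "A2", "A3"))
  css <- classify_css(call_css(cluster_sweeps(cat), cat), cat)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_css(css, tsv, bed)
  back <- read_css(tsv)
  expect_equal(back$css_id, css$css_id)
  expect_equal(back$start, css$start)
  expect_equal(back$classification, css$classification)
  expect_equal(back$member_sweeps, css$member_sweeps)
  bed_tab <- utils::read.delim(bed, header = FALSE)
  expect_equal(nrow(bed_tab), nrow(css))
  expect_equal(bed_tab$V2, css$start - 1)
  # empty input -> header-only TSV, empty BED
  write_css(css[0, ], tsv, bed)
  expect_equal(nrow(read_css(tsv)), 0)
  expect_equal(file.size(bed), 0)
})
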