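test_that("segment files parse, canonicalise and report bad rows", {
  tf <- tempfile(fileext = ".ibd")
  writeLines(c("A\t1\tB\t1\t1\t100\t500\t3.2",
               "C\t2\tB\t1\t1\t300\t700\t0.5",   # out of order pair
               "A\t2\tC\t1\t2\t1000\t2000\t1.1"), tf)
  segs <- read_ibd_segments(tf)
  expect_identical(nrow(segs), 3L)
  expect_true(all(segs$hap_a < segs$hap_b))
  expect_identical(segs$sample1[2], "B")  # swapped into canonical order
  expect_identical(segs$sample2[2], "C")

  writeLines(c("A\t1\tB\t1\t1\t100\t500\t3.2",
               "A\t1\tB\t1\t1\t100"), tf)
  expect_error(read_ibd_segments(tf), "line")
  writeLines("A\t1\tB\t1\t1\txxx\t500\t3.2", tf)
  expect_error(read_ibd_segments(tf), "line")

  writeLines(character(0), tf)
  expect_warning(empty <- read_ibd_segments(tf), "no segment rows")
  expect_identical(nrow(empty), 0L)
})

test_that("write/read round-trips and formats probabilities", {
  segs <- make_segs(list("A", 1, "B", 1, "1", 100, 500, 3.2),
                    list("A", 2, "C", 1, "2", 1000, 2000, 1.1))
  segs$prob <- c(0.987654321, NA)
  tf <- tempfile(fileext = ".ibd")
  write_ibd_segments(segs, tf)
  expect_true(any(grepl("0.987654", readLines(tf), fixed = TRUE)))
  back <- read_ibd_segments(tf)
  expect_equal(back$start_bp, segs$start_bp)
  expect_equal(back$lod, segs$lod)
  expect_equal(back$prob, c(0.987654, NA))
  expect_identical(back$hap_a, segs$hap_a)

  # empty set: header-only file, still readable
  write_ibd_segments(segs[0, ], tf)
  expect_identical(length(readLines(tf)), 1L)
  expect_warning(back0 <- read_ibd_segments(tf))
  expect_identical(nrow(back0), 0L)
})

test_that("filters drop weak and short segments", {
  segs <- make_segs(list("A", 1, "B", 1, "1", 1e6, 1.6e6, 3.0),
                    list("A", 1, "C", 1, "1", 1e6, 1.6e6, 0.05),
                    list("B", 1, "C", 1, "1", 1e6, 1e6 + 9e4, 3.0))
  out <- filter_segments(segs)  # defaults 0.1 LOD / 0.1 cM at 1 cM/Mb
  expect_identical(nrow(out), 1L)
  expect_identical(out$hap_a, "A:1")
  expect_identical(out$hap_b, "B:1")
})

test_that("genetic maps interpolate linearly and read both formats", {
  tf <- tempfile()
  writeLines(c("1\t1000000\t0.0", "1\t2000000\t2.0", "1\t3000000\t2.5"), tf)
  map <- read_genetic_map(tf)
  expect_equal(cm_at(map, "1", 1500000), 1.0)
  expect_equal(cm_at(map, "1", 2500000), 2.25)
  expect_equal(cm_at(map, "1", 5e6), 2.5)  # constant beyond the map
  # PLINK .map: chrom id cM bp
  writeLines(c("1 rs1 0.0 1000000", "1 rs2 2.0 2000000"), tf)
  map2 <- read_genetic_map(tf)
  expect_equal(cm_at(map2, "1", 1500000), 1.0)
  # 1 cM/Mb fallback without a map
  expect_equal(cm_at(NULL, "1", 2.5e6), 2.5)

  segs <- make_segs(list("A", 1, "B", 1, "1", 1000000, 2000000, 3))
  expect_equal(segment_length_cm(segs, map), 2.0)
  expect_equal(segment_length_cm(segs), 1.0)
})

test_that("breakpoints induce the documented half-open intervals", {
  segs <- make_segs(list("A", 1, "B", 1, "1", 100, 500, 3),
                    list("B", 1, "C", 1, "1", 300, 700, 3))
  expect_identical(ibd_breakpoints(segs),
                   list(`1` = c(100, 300, 501, 701)))
  one <- make_segs(list("A", 1, "B", 1, "1", 100, 500, 3))
  expect_identical(ibd_breakpoints(one), list(`1` = c(100, 501)))
  expect_identical(length(ibd_breakpoints(one[0, ])), 0L)
})

test_that("region graphs fill uncalled within-component pairs with the prior", {
  segs <- make_segs(list("A", 1, "B", 1, "1", 100, 500, 3),
                    list("B", 1, "C", 1, "1", 300, 700, 3))
  regions <- build_region_graphs(segs)
  # intervals: [100,300) covered by A-B only; [300,501) by both; [501,701) by B-C
  expect_identical(length(regions), 3L)
  mid <- regions[[2]]
  expect_identical(length(mid$components), 1L)
  G <- mid$components[[1]]$graph
  expect_identical(G$nodes, c("A:1", "B:1", "C:1"))
  expect_equal(G$p["A:1", "C:1"], 0.0046)  # never called: prior
  expect_gt(G$p["A:1", "B:1"], 0.99)       # LOD 3 calibrated + clamped
  expect_false(mid$components[[1]]$called["A:1", "C:1"][1])

  # one segment: a single 2-node graph
  one <- build_region_graphs(make_segs(list("A", 1, "B", 1, "1", 100, 500, 3)))
  expect_identical(length(one), 1L)
  expect_identical(length(one[[1]]$components[[1]]$graph$nodes), 2L)

  # two disjoint pairs in one interval: two components
  two <- build_region_graphs(make_segs(
    list("A", 1, "B", 1, "1", 100, 500, 3),
    list("C", 1, "D", 1, "1", 100, 500, 3)))
  expect_identical(length(two[[1]]$components), 2L)
})

test_that("cross-region merging takes unions and maxima above threshold", {
  pieces <- data.frame(hap_a = "A:1", hap_b = "B:1", chrom = "1",
                       start_bp = c(100, 300), end_bp = c(299, 500),
                       prob = c(0.995, 0.999), stringsAsFactors = FALSE)
  merged <- merge_across_regions(pieces)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$start_bp, 100)
  expect_equal(merged$end_bp, 500)
  expect_equal(merged$prob, 0.999)

  # sub-threshold piece stays separate
  pieces$prob[2] <- 0.95
  expect_identical(nrow(merge_across_regions(pieces)), 2L)

  # different pairs never merge
  pieces2 <- pieces
  pieces2$hap_b <- c("B:1", "C:1")
  pieces2$prob <- c(0.995, 0.999)
  expect_identical(nrow(merge_across_regions(pieces2)), 2L)

  # merging never decreases a probability
  set.seed(55)
  pieces3 <- data.frame(hap_a = "A:1", hap_b = "B:1", chrom = "1",
                        start_bp = seq(1, 901, by = 100),
                        end_bp = seq(100, 1000, by = 100),
                        prob = runif(10, 0.98, 1))
  m3 <- merge_across_regions(pieces3)
  expect_gte(min(m3$prob), min(pieces3$prob))
  expect_equal(max(m3$prob), max(pieces3$prob))
})

test_that("inferred segments take the intersection of member intervals", {
  segs <- make_segs(list("A", 1, "B", 1, "1", 100, 500, 3),
                    list("B", 1, "C", 1, "1", 300, 700, 3))
  regions <- build_region_graphs(segs)
  mid <- regions[[2]]
  G <- mid$components[[1]]$graph
  ph <- matrix(0.995, 3, 3, dimnames = list(G$nodes, G$nodes))
  inf <- infer_new_segments(mid, list(ph), segs)
  expect_identical(nrow(inf), 1L)
  expect_identical(inf$hap_a, "A:1")
  expect_identical(inf$hap_b, "C:1")
  expect_equal(inf$start_bp, 300)
  expect_equal(inf$end_bp, 500)
  expect_true(inf$inferred)
  expect_equal(inf$prob, 0.995)

  # below threshold: nothing
  ph2 <- matrix(0.5, 3, 3, dimnames = list(G$nodes, G$nodes))
  expect_identical(nrow(infer_new_segments(mid, list(ph2), segs)), 0L)

  # single-segment component: no uncalled edges, nothing inferred
  first <- regions[[1]]
  phx <- matrix(1, 2, 2, dimnames = list(first$components[[1]]$graph$nodes,
                                         first$components[[1]]$graph$nodes))
  expect_identical(nrow(infer_new_segments(first, list(phx), segs)), 0L)
})
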