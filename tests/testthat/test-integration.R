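test_that("map_record builds all gene combinations and reports drops", {
  map <- tiny_mapping(6, ambiguous = c(1, 2))
  rec <- tiny_records("S1", "S3", pmids = list("1"))
  m <- map_record(rec, map)
  expect_true(m$mapped)
  expect_equal(nrow(m$gene_combinations), 2L)  # {g1,g101} x {g3}

  rec2 <- tiny_records("S1", "S2")
  m2 <- map_record(rec2, map)
  expect_equal(nrow(m2$gene_combinations), 4L)  # 2 x 2 cross product

  m3 <- map_record(tiny_records("S1", "NOPE"), map)
  expect_false(m3$mapped)
  expect_match(m3$reason, "unmappable")

  expect_error(map_record(rec, tiny_mapping(0)), "empty identifier mapping")
})

test_that("duplicate pairs across sources union their evidence", {
  map <- tiny_mapping(4)
  dX <- tiny_records("S1", "S2", pmids = list("1"),
                     techs = list("Two-hybrid"), source = "X")
  dY <- tiny_records("S2", "S1", pmids = list("2"),
                     techs = list("two hybrid"), source = "Y")
  net <- merge_sources(list(dX, dY), map)
  expect_equal(nrow(net), 1L)
  expect_equal(net$studies[[1]], c("1", "2"))
  expect_equal(net$techniques[[1]], "Two-hybrid")  # one canonical technique
  expect_equal(net$sources[[1]], c("X", "Y"))
})

test_that("genetic records and unmappable endpoints are excluded", {
  map <- tiny_mapping(4)
  d <- rbind(tiny_records("S1", "S2", pmids = list("1")),
             tiny_records("S3", "S4", pmids = list("2"), genetic = TRUE),
             tiny_records("S1", "ZZZ", pmids = list("3")))
  class(d) <- c("hippie_records", "data.frame")
  net <- merge_sources(d, map)
  expect_equal(nrow(net), 1L)
  expect_equal(attr(net, "n_genetic"), 1L)
  drops <- attr(net, "drops")
  expect_equal(nrow(drops), 1L)
  expect_match(drops$reason, "second endpoint")
})

test_that("ortholog evidence boosts existing pairs but never creates them", {
  map <- tiny_mapping(4)
  d <- tiny_records("S1", "S2", pmids = list("1"))
  orth <- data.frame(protein_a = c("P01", "P03"),
                     protein_b = c("P02", "P04"),
                     species = c("Mus musculus", "Rattus norvegicus"),
                     stringsAsFactors = FALSE)
  net <- merge_sources(d, map, orthologs = orth)
  expect_equal(nrow(net), 1L)  # ortholog-only pair (P03,P04) discarded
  expect_equal(net$organisms[[1]], "Mus musculus")
  expect_equal(attr(net, "ortholog_only"), 1L)

  bad <- data.frame(protein_a = "P01", protein_b = "P02",
                    species = "Homo sapiens", stringsAsFactors = FALSE)
  expect_error(merge_sources(d, map, orthologs = bad), "Homo sapiens")
})

test_that("merging is idempotent and order/duplication-invariant", {
  for (seed in 1:5) {
    fx <- generate_sources(synthetic_spec(n_proteins = 20,
                                          n_interactions = 35, seed = seed))
    ref <- merge_sources(fx$datasets, fx$mapping, orthologs = fx$orthologs)
    perm <- merge_sources(rev(fx$datasets), fx$mapping,
                          orthologs = fx$orthologs)
    dup <- merge_sources(c(fx$datasets, fx$datasets[1]), fx$mapping,
                         orthologs = fx$orthologs)
    strip <- function(x) {
      attributes(x) <- attributes(x)[c("names", "row.names", "class")]
      x
    }
    expect_identical(strip(perm), strip(ref))
    expect_identical(strip(dup), strip(ref))
    expect_identical(attr(perm, "provenance"), attr(ref, "provenance"))
    # |output| <= sum of inputs
    expect_lte(nrow(ref), sum(vapply(fx$datasets, nrow, integer(1))))
  }
})

test_that("evidence is conserved through mapping and merging", {
  fx <- generate_sources(synthetic_spec(seed = 17))
  net <- merge_sources(fx$datasets, fx$mapping, orthologs = fx$orthologs)
  tr <- fx$truth$pairs
  expect_equal(nrow(net), nrow(tr))
  m <- match(paste(net$protein_a, net$protein_b),
             paste(tr$protein_a, tr$protein_b))
  expect_false(anyNA(m))
  cnt <- evidence_counts(net)
  expect_equal(cnt$n_studies, tr$n_studies[m])
  expect_equal(cnt$n_organisms, tr$n_organisms[m])
  expect_identical(net$techniques, tr$techniques[m])
  expect_true(all(lengths(net$sources) >= 1L))
})

test_that("self-interactions survive and a no-study record still counts techniques", {
  map <- tiny_mapping(3)
  d <- rbind(tiny_records("S1", "S1", pmids = list("1"),
                          techs = list("Two-hybrid")),
             tiny_records("S2", "S3", techs = list("FRET")))
  class(d) <- c("hippie_records", "data.frame")
  net <- merge_sources(d, map)
  expect_equal(nrow(net), 2L)
  expect_equal(net$protein_a[1], net$protein_b[1])
  cnt <- evidence_counts(net)
  i <- which(net$protein_a == "P02")
  expect_equal(cnt$n_studies[i], 0L)       # no PubMed id
  expect_equal(cnt$technique_mass[i], 6)   # FRET still scores
})
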