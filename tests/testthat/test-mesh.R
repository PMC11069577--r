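toy_hierarchy <- function() {
  load_hierarchy(data.frame(
    term_id = c("NERV", "NEURO", "DEMYEL", "MS", "CARDIO", "DUAL"),
    name = c("Nervous system diseases", "Neurodegenerative",
             "Demyelinating", "Multiple sclerosis",
             "Cardiovascular diseases", "Dual-parent disorder"),
    tree_numbers = c("C10", "C10.228", "C10.228.140", "C10.228.140.300",
                     "C14", "C10.900;C14.100"),
    stringsAsFactors = FALSE
  ))
}

test_that("hierarchy levels follow dotted tree-number depth", {
  h <- toy_hierarchy()
  expect_equal(mesh_level(h, "NERV"), 1)
  expect_equal(mesh_level(h, "NEURO"), 2)
  expect_equal(mesh_level(h, "DEMYEL"), 3)
  expect_equal(mesh_level(h, "DUAL"), 2)  # minimum depth across trees
  expect_equal(mesh_level(h, "Not found"), 1)
  expect_error(mesh_level(h, "NOPE"), "unknown term")
})

test_that("orphan tree numbers are rejected", {
  expect_error(load_hierarchy(data.frame(
    term_id = c("A", "B"), name = c("a", "b"),
    tree_numbers = c("C01", "C99.100")
  )), "orphan")
})

test_that("ancestor rollup reaches every top-level heading", {
  h <- toy_hierarchy()
  expect_equal(ancestors_to_top(h, "DEMYEL"), "NERV")
  expect_equal(ancestors_to_top(h, "MS"), "NERV")
  expect_setequal(ancestors_to_top(h, "DUAL"), c("NERV", "CARDIO"))
  expect_equal(ancestors_to_top(h, "Not found"), "Not found")
})

test_that("headings count at most once per variant", {
  h <- toy_hierarchy()
  mapping <- data.frame(
    condition = c("ms", "demyel", "dual", "neuro"),
    term_id = c("MS", "DEMYEL", "DUAL", "NEURO"),
    stringsAsFactors = FALSE
  )
  variants <- data.frame(
    allele_id = c("1", "2", "3", "4"),
    conditions = c("ms|demyel",   # two conditions under the same top: 1
                   "dual",        # two tops: counts once each
                   "mystery",     # unmapped: Not found
                   "not provided"),
    stringsAsFactors = FALSE
  )
  counts <- count_headings(variants, mapping, h)
  expect_equal(counts$count[counts$heading == "NERV"], 2)   # variants 1, 2
  expect_equal(counts$count[counts$heading == "CARDIO"], 1)
  expect_equal(counts$count[counts$heading == "Not found"], 1)
  expect_true(all(counts$count <= nrow(variants)))
})

test_that("qualified mappings fall back to Not found", {
  h <- toy_hierarchy()
  mapping <- data.frame(
    condition = c("good", "bad"), term_id = c("MS", "MS"),
    qualifier = c("", "abnormalities"), stringsAsFactors = FALSE
  )
  variants <- data.frame(allele_id = c("1", "2"),
                         conditions = c("good", "bad"))
  counts <- count_headings(variants, mapping, h)
  expect_equal(counts$count[counts$heading == "NERV"], 1)
  expect_equal(counts$count[counts$heading == "Not found"], 1)
})

test_that("adding a condition never decreases any heading count", {
  h <- toy_hierarchy()
  mapping <- data.frame(condition = c("ms", "dual"),
                        term_id = c("MS", "DUAL"))
  v1 <- data.frame(allele_id = "1", conditions = "ms")
  v2 <- data.frame(allele_id = "1", conditions = "ms|dual")
  c1 <- count_headings(v1, mapping, h)
  c2 <- count_headings(v2, mapping, h)
  for (i in seq_len(nrow(c1))) {
    expect_gte(c2$count[c2$heading == c1$heading[i]], c1$count[i])
  }
})

test_that("third-level coverage counts grandchild terms and descendants", {
  fx <- make_mesh_fixture(depth = 4, branching = 2, seed = 70)
  h <- load_hierarchy(fx$hierarchy)
  top <- fx$manifest$top_terms[1]
  third <- h$tree$term_id[h$tree$depth == 3 &
                            startsWith(h$tree$tree_number,
                                       paste0(h$tns_of_term[[top]], "."))]
  expect_length(third, 4)  # branching 2: 4 grandchildren per top term

  # predicted site on one third-level term; C>U-only site on a fourth-level
  # child of a different third-level term
  fourth_tn <- h$tree$tree_number[h$tree$depth == 4 &
                                    startsWith(h$tree$tree_number,
                                               h$tns_of_term[[third[2]]])][1]
  fourth <- h$term_of_tn[[fourth_tn]]
  cov <- third_level_coverage(h, top,
                              c2u_terms = c(third[1], fourth),
                              predicted_terms = third[1])
  expect_equal(cov$n_terms, 4)
  expect_equal(cov$pct_predicted, 25)   # 1 of 4
  expect_equal(cov$pct_c2u_only, 25)    # fourth-level site covers its
                                        # third-level ancestor, no prediction

  # terms with no grandchildren yield NA percentages
  deep <- h$tree$term_id[h$tree$depth == 3][1]
  none <- third_level_coverage(h, deep, character(0), character(0))
  expect_equal(none$n_terms, 0)
  expect_true(is.na(none$pct_predicted))
})

test_that("coverage by prediction never exceeds coverage by any site", {
  fx <- make_mesh_fixture(depth = 4, branching = 3, seed = 71)
  h <- load_hierarchy(fx$hierarchy)
  set.seed(72)
  for (i in 1:10) {
    all_terms <- h$terms$term_id
    c2u_terms <- sample(all_terms, 6)
    predicted_terms <- sample(c2u_terms, 2)
    top <- fx$manifest$top_terms[1]
    cov <- third_level_coverage(h, top, c2u_terms, predicted_terms)
    both <- third_level_coverage(h, top, c2u_terms, c2u_terms)
    expect_lte(cov$pct_predicted, both$pct_predicted)
  }
})

test_that("heading tables split by set and pathogenicity scope", {
  h <- toy_hierarchy()
  mapping <- data.frame(condition = c("ms", "dual"),
                        term_id = c("MS", "DUAL"))
  variants <- data.frame(
    allele_id = c("1", "2", "3"),
    conditions = c("ms", "dual", "ms"),
    bin = c("pathogenic", "benign", "pathogenic"),
    predicted = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  tab <- heading_count_table(variants, mapping, h)
  c2u_path <- tab[tab$set == "c2u_set" & tab$scope == "pathogenic", ]
  expect_equal(c2u_path$count[c2u_path$heading == "NERV"], 2)
  pred_all <- tab[tab$set == "predicted_set" & tab$scope == "all", ]
  expect_equal(pred_all$count[pred_all$heading == "NERV"], 1)
  expect_false("CARDIO" %in% pred_all$heading)
})
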