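test_roles <- function(asg, fold) {
  a <- asg$assignment
  split(paste(a$cell_id, a$drug_id), a$role[a$fold == fold])
}

test_that("random split deals pairs evenly, deterministically, down to leave-one-out", {
  ds <- toy_grid(5, 2)  # 10 pairs
  asg <- split_random(ds, split_spec("random", k = 5, seed = 3))
  a <- asg$assignment
  test_sizes <- table(a$fold[a$role == "test"])
  expect_true(all(test_sizes == 2))
  tested <- unique(paste(a$cell_id, a$drug_id)[a$role == "test"])
  expect_setequal(tested, paste(ds$cell_id, ds$drug_id))
  # same seed reproduces; different seed differs
  asg2 <- split_random(ds, split_spec("random", k = 5, seed = 3))
  expect_identical(asg$assignment, asg2$assignment)
  asg3 <- split_random(ds, split_spec("random", k = 5, seed = 4))
  expect_false(identical(asg$assignment, asg3$assignment))
  # boundary: k = n pairs is leave-one-pair-out
  loo <- split_random(ds, split_spec("random", k = 10, seed = 1))
  expect_true(all(table(loo$assignment$fold[loo$assignment$role == "test"]) == 1))
  expect_error(split_random(ds, split_spec("random", k = 11, seed = 1)),
               "exceeds")
  # validation carve-out comes from the training side
  val <- split_random(ds, split_spec("random", k = 5, seed = 1,
                                     validation_fraction = 0.25))
  v <- val$assignment
  expect_true(all(table(v$fold[v$role == "validation"]) == 2))  # floor(0.25*8)
})

test_that("cell-blind folds hold out whole cells, balanced by cell count", {
  ds <- toy_grid(6, 4)
  asg <- split_cell_blind(ds, split_spec("cell_blind", k = 3, seed = 9))
  a <- asg$assignment
  for (f in 0:2) {
    test_cells <- unique(a$cell_id[a$fold == f & a$role == "test"])
    train_cells <- unique(a$cell_id[a$fold == f & a$role == "train"])
    expect_length(test_cells, 2)
    expect_length(intersect(test_cells, train_cells), 0)
    expect_equal(sum(a$fold == f & a$role == "test"), 8)  # 2 cells x 4 drugs
  }
  expect_true(all_checks_pass(verify_assignment(ds, asg)))
  # unbalanced pair counts per cell: balance is by cells, not pairs
  sparse <- ds[-c(1, 2, 3, 7), ]
  sp <- triplet_dataset(as.data.frame(sparse), name = "sp")
  asg2 <- split_cell_blind(sp, split_spec("cell_blind", k = 3, seed = 9))
  counts <- sapply(0:2, function(f) {
    a2 <- asg2$assignment
    length(unique(a2$cell_id[a2$fold == f & a2$role == "test"]))
  })
  expect_lte(diff(range(counts)), 1)
  # boundary: leave-one-cell-line-out
  loco <- split_cell_blind(ds, split_spec("cell_blind", k = 6, seed = 1))
  expect_true(all_checks_pass(verify_assignment(ds, loco)))
  expect_error(split_cell_blind(ds, split_spec("cell_blind", k = 7, seed = 1)),
               "exceeds")
})

test_that("drug-blind folds are symmetric to cell-blind with drugs as units", {
  ds <- toy_grid(4, 6)
  asg <- split_drug_blind(ds, split_spec("drug_blind", k = 3, seed = 2))
  a <- asg$assignment
  drug_folds <- tapply(a$fold[a$role == "test"],
                       a$drug_id[a$role == "test"],
                       function(f) length(unique(f)))
  expect_true(all(drug_folds == 1))  # no drug is test in two folds
  for (f in 0:2) {
    expect_equal(sum(a$fold == f & a$role == "test"), 8)  # 2 drugs x 4 cells
  }
  expect_identical(
    split_drug_blind(ds, split_spec("drug_blind", k = 3, seed = 2))$assignment,
    a)
  expect_true(all_checks_pass(verify_assignment(ds, asg)))
})

test_that("completely-blind 4x4/k=2 matches the brute-force enumeration", {
  ds <- toy_grid(4, 4)
  asg <- split_completely_blind(ds, split_spec("completely_blind", k = 2, seed = 5))
  a <- asg$assignment
  # brute-force oracle: recover the entity groups from the test blocks and
  # enumerate all 16 pairs
  for (f in 0:1) {
    test_cells <- unique(a$cell_id[a$fold == f & a$role == "test"])
    test_drugs <- unique(a$drug_id[a$fold == f & a$role == "test"])
    expect_length(test_cells, 2)
    expect_length(test_drugs, 2)
    expected_role <- function(cell, drug) {
      if (cell %in% test_cells && drug %in% test_drugs) "test"
      else if (!(cell %in% test_cells) && !(drug %in% test_drugs)) "train"
      else "discarded"
    }
    grid <- expand.grid(cell = unique(ds$cell_id), drug = unique(ds$drug_id),
                        stringsAsFactors = FALSE)
    oracle <- mapply(expected_role, grid$cell, grid$drug)
    got <- a$role[a$fold == f][match(paste(grid$cell, grid$drug),
                                     paste(a$cell_id, a$drug_id)[a$fold == f])]
    expect_identical(unname(got), unname(oracle))
    expect_equal(as.vector(table(factor(got, c("test", "train", "discarded")))),
                 c(4L, 4L, 8L))
  }
  # combined test coverage is 1/k of the grid on divisible grids
  expect_equal(sum(a$role == "test"), 8)  # 16 pairs / k=2
  expect_true(all_checks_pass(verify_assignment(ds, asg)))
})

test_that("completely-blind counts follow ((k-1)/k)^2 train fraction on divisible grids", {
  ds <- toy_grid(9, 9)
  asg <- split_completely_blind(ds, split_spec("completely_blind", k = 3, seed = 1))
  a <- asg$assignment
  for (f in 0:2) {
    expect_equal(sum(a$fold == f & a$role == "test"), 9)       # (9/3)^2
    expect_equal(sum(a$fold == f & a$role == "train"), 36)     # (6)^2
  }
  expect_equal(sum(a$role == "test"), 27)  # 81/3 across folds
})

test_that("cancer-type-blind follows the greedy trace and keeps types whole", {
  # 3 types with 4, 3, 3 cells; greedy: largest -> fold 0, next two -> fold 1
  types <- c(rep("big", 4), rep("midA", 3), rep("midB", 3))
  ds <- toy_grid(10, 3, types = types)
  asg <- split_cancer_type_blind(ds, split_spec("cancer_type_blind", k = 2, seed = 1))
  a <- asg$assignment
  cells_per_fold <- sapply(0:1, function(f)
    length(unique(a$cell_id[a$fold == f & a$role == "test"])))
  expect_setequal(cells_per_fold, c(4, 6))
  type_of <- types[match(unique(ds$cell_id), unique(ds$cell_id))]
  v <- verify_assignment(ds, asg)
  expect_true(all_checks_pass(v))
  expect_true(v$pass[v$check == "type_cohesion"])
  # cells with missing type are excluded and counted
  types_na <- types; types_na[1] <- NA
  ds2 <- toy_grid(10, 3, types = types_na)
  expect_message(
    asg2 <- split_cancer_type_blind(ds2, split_spec("cancer_type_blind",
                                                    k = 2, seed = 1)),
    "excluded 1 cell")
  expect_equal(asg2$notes$excluded_cells, "C01")
  a2 <- asg2$assignment
  expect_true(all(a2$role[a2$cell_id == "C01"] == "discarded"))
  expect_true(all_checks_pass(verify_assignment(ds2, asg2)))
  expect_error(split_cancer_type_blind(
    ds, split_spec("cancer_type_blind", k = 4, seed = 1)), "exceeds")
})

test_that("verify_assignment detects deliberate violations", {
  ds <- toy_grid(6, 4)
  asg <- split_cell_blind(ds, split_spec("cell_blind", k = 3, seed = 9))
  # move one test cell's pairs into training for fold 0
  bad <- asg
  a <- bad$assignment
  victim <- a$cell_id[a$fold == 0 & a$role == "test"][1]
  a$role[a$fold == 0 & a$cell_id == victim][1] <- "train"
  bad$assignment <- a
  v <- verify_assignment(ds, bad)
  expect_false(all_checks_pass(v))
  expect_false(v$pass[v$check == "cell_disjointness"])
  expect_match(v$detail[v$check == "cell_disjointness"], victim)
  # negative control: a random assignment fails cell-blind rules
  rnd <- split_random(ds, split_spec("random", k = 3, seed = 1))
  v2 <- verify_assignment(ds, rnd, strategy = "cell_blind")
  expect_false(v2$pass[v2$check == "cell_disjointness"])
})

test_that("all strategies verify across random sparse datasets (property sample)", {
  for (i in 1:15) {
    cfg <- withr::with_seed(3000 + i, {
      screen_config(n_cells = sample(6:25, 1), n_drugs = sample(6:25, 1),
                    n_types = sample(3:5, 1),
                    missing_fraction = runif(1, 0, 0.35),
                    seed = 3000 + i)
    })
    sim <- generate_screen(cfg)
    k <- 3
    for (strategy in c("random", "cell_blind", "drug_blind",
                       "completely_blind", "cancer_type_blind")) {
      asg <- split_dataset(sim$dataset,
                           split_spec(strategy, k = k, seed = i,
                                      validation_fraction = 0.1))
      expect_true(all_checks_pass(verify_assignment(sim$dataset, asg)),
                  label = sprintf("%s on dataset %d", strategy, i))
    }
  }
})

test_that("assignment_table exports compact or expanded rows", {
  ds <- toy_grid(4, 3)
  asg <- split_random(ds, split_spec("random", k = 3, seed = 1,
                                     validation_fraction = 0.2))
  compact <- assignment_table(asg)
  expect_setequal(unique(compact$role), c("test", "validation"))
  full <- assignment_table(asg, expand_train = TRUE)
  expect_equal(nrow(full), 12 * 3)
  expect_setequal(unique(full$role), c("test", "validation", "train"))
})
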