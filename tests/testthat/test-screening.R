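test_that("an exact copy of the query ranks first", {
  set.seed(2)
  q <- randomTestMolecule(10, name = "query")
  copy <- newMolecule("thecopy", atomCoords(q), atomCharges(q))
  others <- lapply(1:3, function(i)
    randomTestMolecule(10, name = sprintf("other_%d", i)))
  res <- screen(q, c(list(copy), others))
  expect_identical(res$name[1L], "thecopy")
  # rank 1 really is the maximum: compare against direct scores
  qd <- encodeMolecule(q, 0.005)
  direct <- vapply(c(list(copy), others), function(m)
    ccScore(qd, encodeMolecule(m, 0.005)), 0)
  expect_equal(res$score[1L], max(direct))
})

test_that("conformer filtering keeps the best-scoring record per name", {
  set.seed(4)
  q <- randomTestMolecule(8, name = "q")
  confs <- lapply(1:3, function(i)
    jitterMolecule(newMolecule("mol_A", atomCoords(q), atomCharges(q)),
                   coordSd = 0.2 * i, chargeSd = 0))
  res <- screen(q, confs, dedup = TRUE)
  expect_identical(nrow(res), 1L)
  resAll <- screen(q, confs, dedup = FALSE)
  expect_identical(nrow(resAll), 3L)
  expect_equal(res$score, max(resAll$score))
  # dedup is idempotent: rescreening the winner changes nothing
  expect_identical(res$rank, 1L)
})

test_that("ranks are dense, scores non-increasing, ties keep input order", {
  set.seed(6)
  q <- randomTestMolecule(8, name = "q")
  db <- lapply(1:12, function(i)
    randomTestMolecule(8, name = sprintf("m_%02d", i)))
  res <- screen(q, db, dedup = FALSE)
  expect_identical(res$rank, seq_len(nrow(res)))
  expect_true(all(diff(res$score) <= 0))
  # order independence: per-name scores are unchanged by database order
  # (tied ranks follow input order by design, so only the mapping and the
  # sorted score sequence are order-free)
  res2 <- screen(q, db[sample(length(db))], dedup = FALSE)
  expect_identical(sort(res2$score, decreasing = TRUE), res$score)
  expect_identical(res2$score[match(res$name, res2$name)], res$score)
})

test_that("screening accepts a MOL2 path and an empty database", {
  set.seed(8)
  q <- randomTestMolecule(6, name = "q")
  db <- lapply(1:4, function(i)
    randomTestMolecule(6, name = sprintf("db_%d", i)))
  f <- withr::local_tempfile(fileext = ".mol2")
  writeMol2(db, f)
  fromFile <- screen(q, f)
  fromList <- screen(q, readMol2(f))
  expect_equal(fromFile, fromList)
  # the 1e-6 MOL2 round-trip moves scores by at most ~1e-3 relative
  direct <- screen(q, db)
  expect_identical(fromFile$name, direct$name)
  expect_equal(fromFile$score, direct$score, tolerance = 1e-3)

  empty <- screen(q, list())
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("name", "score", "rank", "active"))
})

test_that("streaming scores match the in-memory screen with dedup off", {
  set.seed(10)
  q <- randomTestMolecule(8, name = "q")
  db <- lapply(1:15, function(i)
    randomTestMolecule(sample(4:10, 1), name = sprintf("m_%d", i)))
  f <- withr::local_tempfile(fileext = ".mol2")
  writeMol2(db, f)
  out <- withr::local_tempfile()
  n <- screenStreaming(q, f, sink = out)
  expect_identical(n, 15L)
  lines <- readLines(out)
  expect_true(startsWith(lines[1L], "# query=q"))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  expect_identical(vapply(body, `[[`, "", 1L), paste0("m_", 1:15))
  streamed <- as.numeric(vapply(body, `[[`, "", 2L))
  inmem <- screen(q, readMol2(f), dedup = FALSE)
  expect_identical(sort(streamed), sort(inmem$score))

  emptyOut <- withr::local_tempfile()
  expect_identical(screenStreaming(q, list(), sink = emptyOut), 0L)
  expect_length(readLines(emptyOut), 1L)   # header only
})

test_that("labelActives flags exactly the prefixed names", {
  rec <- data.frame(name = c("active_lig1", "decoy_7", "act", "active"),
                    score = c(4, 3, 2, 1), rank = 1:4, active = NA)
  out <- labelActives(rec)
  expect_identical(out$active, c(TRUE, FALSE, FALSE, TRUE))
  none <- labelActives(rec, prefix = "ZZZ")
  expect_false(any(none$active))
  set.seed(12)
  names <- ifelse(runif(50) < 0.3, sprintf("active_%d", 1:50),
                  sprintf("decoy_%d", 1:50))
  rec2 <- data.frame(name = names, score = runif(50), rank = 1:50,
                     active = NA)
  out2 <- labelActives(rec2)
  expect_identical(sum(out2$active), sum(grepl("^active", names)))
  expect_identical(out2$name, rec2$name)   # nothing else altered
  expect_identical(out2$score, rec2$score)
})

test_that("writeScores emits a harvestable header and one row per record", {
  set.seed(14)
  q <- randomTestMolecule(5, name = "q")
  res <- screen(q, lapply(1:3, function(i)
    randomTestMolecule(5, name = sprintf("m_%d", i))))
  f <- withr::local_tempfile()
  writeScores(res, f, query = q, dx = 0.005, scorer = "CC", auc = 0.75)
  lines <- readLines(f)
  expect_match(lines[1L], "query=q dx=0.005 scorer=CC auc=0.750000")
  expect_identical(length(lines), 2L + nrow(res))
})
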