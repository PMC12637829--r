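test_that("write/read round-trips preserve atoms and coordinates", {
  sp <- ideal_fibril_spec(strrep("A", 24), path = "U_bend",
                          rise = 4.8, twist = -1.8, n_layers = 3)
  model <- make_ideal_fibril(sp)$model
  for (ext in c("cif", "pdb")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_structure(model, f)
    back <- read_structure(f)
    expect_equal(nrow(back$atoms), nrow(model$atoms))
    expect_equal(length(unique(back$atoms$chain)),
                 length(unique(model$atoms$chain)))
    expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                        as.matrix(model$atoms[, c("x", "y", "z")]))),
              1e-3)
  }
})

test_that("a file with only water molecules is an empty model", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(read_structure(f), "empty model")
})

test_that("vdW radii are assigned from the documented table", {
  sp <- ideal_fibril_spec("AAAA", path = "linear", n_layers = 1)
  m <- make_ideal_fibril(sp)$model
  r <- vdw_radii()
  expect_equal(unique(m$atoms$vdw[m$atoms$element == "C"]), r[["C"]])
  expect_equal(unique(m$atoms$vdw[m$atoms$element == "O"]), r[["O"]])
  expect_true(all(m$atoms$vdw > 0))
})

test_that("layer ordering follows the axis and is permutation-invariant", {
  sp <- ideal_fibril_spec(strrep("A", 12), path = "linear",
                          rise = 4.8, twist = 0, n_layers = 5)
  m <- make_ideal_fibril(sp)$model
  m <- order_layers(m, fibril_axis(c(0, 0, 0), c(0, 0, 1)))
  zs <- vapply(m$layers, function(ch)
    mean(m$atoms$z[m$atoms$chain == ch]), numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_equal(m$central, 3L)  # 1-based central layer of a 5-stack

  # shuffle the atom rows: ordering must not change
  set.seed(42)
  shuf <- m
  shuf$atoms <- shuf$atoms[sample(nrow(shuf$atoms)), ]
  shuf$layers <- NULL
  shuf <- order_layers(shuf, fibril_axis(c(0, 0, 0), c(0, 0, 1)))
  expect_identical(shuf$layers, m$layers)
})

test_that("an even stack takes the lower of the two middle layers", {
  sp <- ideal_fibril_spec(strrep("A", 12), path = "linear",
                          rise = 4.8, twist = 0, n_layers = 4)
  m <- order_layers(make_ideal_fibril(sp)$model,
                    fibril_axis(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(m$central, 2L)
})

test_that("ordered spans match a brute-force run-length scan", {
  # the printed-span fixture: residues 4..35 and 47..53 modeled
  xyz <- cbind(seq_len(39) * 3.8, 0, 0)
  at <- make_atoms("A", c(4:35, 47:53), "CA", xyz)
  m <- fibril_model(at)
  sp <- ordered_spans(m, "A")
  expect_equal(vapply(sp, function(s) c(s$first, s$last), integer(2)),
               matrix(c(4L, 35L, 47L, 53L), 2))

  set.seed(7)
  for (i in 1:50) {
    res <- sort(sample(1:100, sample(1:60, 1)))
    m2 <- fibril_model(make_atoms("A", res, "CA",
                                  cbind(seq_along(res) * 3.8, 0, 0)))
    got <- ordered_spans(m2, "A")
    # brute force: walk the sorted residues counting runs
    runs <- split(res, cumsum(c(1, diff(res) > 1)))
    expect_equal(vapply(got, function(s) c(s$first, s$last), integer(2)),
                 vapply(runs, function(r) c(min(r), max(r)), integer(2)),
                 ignore_attr = TRUE)
  }
})

test_that("span residue counts follow the inclusive convention", {
  expect_equal(count_span_residues(list(residue_span(69, 132))), 64L)
  expect_equal(count_span_residues(list(residue_span(4, 38),
                                        residue_span(108, 115))), 43L)
  expect_equal(count_span_residues(list()), 0L)
  expect_equal(count_span_residues(residue_span(5, 5)), 1L)
  expect_error(count_span_residues(list(residue_span(1, 10),
                                        residue_span(5, 20))),
               "overlap")
  expect_error(residue_span(10, 5))
})

test_that("chains with different residue sets trigger a heterogeneity warning", {
  a <- rbind(make_atoms("A", 1:6, "CA", cbind(1:6 * 3.8, 0, 0)),
             make_atoms("B", 3:8, "CA", cbind(1:6 * 3.8, 0, 4.8)))
  m <- fibril_model(a)
  expect_warning(order_layers(m, fibril_axis(c(0, 0, 0), c(0, 0, 1))),
                 "non-identical residue sets")
})
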