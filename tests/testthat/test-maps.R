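# Hand-built fixture: three Tm1 cells on collinear columns feeding target t,
# plus a disynaptic chain through a non-hexel intermediary.
bar_fixture <- function() {
  cells <- data.frame(
    id = c("tm1_a", "tm1_b", "tm1_c", "x1", "t"),
    type = c("Tm1", "Tm1", "Tm1", "X", "Tgt"))
  ed <- data.frame(pre = c("tm1_a", "tm1_b", "tm1_c", "tm1_a", "x1"),
                   post = c("t", "t", "t", "x1", "t"),
                   count = c(5, 9, 5, 4, 2))
  conn <- connectome(cells, ed)
  asg <- lattice_assignment(c("tm1_a", "tm1_b", "tm1_c"),
                            c(-1L, 0L, 1L), c(-1L, 0L, 1L), type = "Tm1")
  list(conn = conn, asg = asg)
}

test_that("monosynaptic map places synapse counts at source positions", {
  fx <- bar_fixture()
  m <- mono_map_cell(fx$conn, fx$asg, "Tm1", "t")
  expect_equal(map_total(m), 19)
  expect_equal(map_lookup(m, c(-1, 0, 1), c(-1, 0, 1)), c(5, 9, 5))
  expect_error(mono_map_cell(fx$conn, fx$asg, "Tm1", "nope"), "unknown cell")
  # no connected source cells -> empty map
  m0 <- mono_map_cell(fx$conn, fx$asg, "Tm1", "tm1_a")
  expect_equal(nrow(m0), 0)
})

test_that("input-fraction mode yields 1.0 for a sole input", {
  cells <- data.frame(id = c("s", "b"), type = c("Tm1", "B"))
  conn <- connectome(cells, data.frame(pre = "s", post = "b", count = 3))
  asg <- lattice_assignment("s", 2L, 1L, type = "Tm1")
  m <- mono_map_cell(conn, asg, "Tm1", "b", weight_mode = "input_fraction")
  expect_equal(map_lookup(m, 2, 1), 1.0)
  expect_identical(attr(m, "unit"), "probability")
})

test_that("disynaptic map weights are products of input fractions", {
  fx <- bar_fixture()
  # P[tm1_a, x1] = 1 (sole input), P[x1, t] = 2/21
  m <- di_map_cell(fx$conn, fx$asg, "Tm1", "X", "t")
  expect_equal(map_lookup(m, -1, -1), 2 / 21)
  # unique chain with full fractions -> weight 1 at the source position
  cells <- data.frame(id = c("a", "b", "c"), type = c("A", "B", "C"))
  conn <- connectome(cells, data.frame(pre = c("a", "b"), post = c("b", "c"),
                                       count = c(2, 7)))
  asg <- lattice_assignment("a", 0L, 0L, type = "A")
  expect_equal(map_lookup(di_map_cell(conn, asg, "A", "B", "c"), 0, 0), 1.0)
})

test_that("trisynaptic map multiplies three fractions", {
  cells <- data.frame(id = c("a", "b", "c", "d", "b2", "c2"),
                      type = c("A", "B", "C", "D", "B", "C"))
  ed <- data.frame(pre = c("a", "a", "b", "b2", "c", "c2"),
                   post = c("b", "b2", "c", "c2", "d", "d"),
                   count = c(1, 1, 1, 1, 1, 1))
  conn <- connectome(cells, ed)
  asg <- lattice_assignment("a", 1L, 2L, type = "A")
  m <- tri_map_cell(conn, asg, "A", "B", "C", "d")
  # two parallel B -> C routes, each carrying 1 * 1 * 0.5
  expect_equal(map_total(m), 1.0)
  expect_equal(map_lookup(m, 1, 2), 1.0)
  # fractions 0.5 at each step along a unique chain multiply to 0.125
  cells2 <- data.frame(
    id = c("a", "b", "c", "d", "o1", "o2", "o3"),
    type = c("A", "B", "C", "D", "Other", "Other", "Other"))
  ed2 <- data.frame(pre = c("a", "o1", "b", "o2", "c", "o3"),
                    post = c("b", "b", "c", "c", "d", "d"),
                    count = 1)
  conn2 <- connectome(cells2, ed2)
  asg2 <- lattice_assignment("a", 0L, 0L, type = "A")
  m2 <- tri_map_cell(conn2, asg2, "A", "B", "C", "d")
  expect_equal(map_lookup(m2, 0, 0), 0.125)
})

test_that("di/tri maps are probability distributions over the full roster", {
  for (seed in c(2, 3)) {
    fx <- random_connectome(n_cells = 50, n_types = 5, seed = seed)
    P <- suppressMessages(input_fractions(fx$conn$W, quiet = TRUE))
    tgt <- fx$conn$cells$id[1]
    tot2 <- 0; tot3 <- 0
    for (A in fx$types) for (B in fx$types) {
      tot2 <- tot2 + map_total(
        di_map_cell(fx$conn, fx$assigns[[A]], A, B, tgt, P = P))
      for (C in fx$types)
        tot3 <- tot3 + map_total(
          tri_map_cell(fx$conn, fx$assigns[[A]], A, B, C, tgt, P = P))
    }
    expect_equal(tot2, 1, tolerance = 1e-9)
    expect_equal(tot3, 1, tolerance = 1e-9)
  }
})

test_that("centre filter weighs the central column by 1.1", {
  fx <- bar_fixture()
  m <- mono_map_cell(fx$conn, fx$asg, "Tm1", "t")
  # filtered value at origin: 1.1*9 + 5 + 5 = 19.9, strictly the largest
  expect_equal(centre_of_map(m), c(p = 0, q = 0))
  # single hexel
  expect_equal(centre_of_map(hexel_map(3, -2, 1)), c(p = 3, q = -2))
  # tie between isolated equal hexels broken by smallest (p+q, p)
  tie <- hexel_map(c(0, 3), c(0, 3), c(4, 4))
  expect_equal(centre_of_map(tie), c(p = 0, q = 0))
  expect_error(centre_of_map(hexel_map()), "empty")
})

test_that("align_and_average reproduces identical and translated maps", {
  m <- hexel_map(c(0, 1, 0), c(0, 1, -1), c(4, 2, 1))
  avg <- align_and_average(list(m, m, m), list(c(0, 0), c(0, 0), c(0, 0)),
                           window_radius = 3)
  expect_equal(as.data.frame(avg$mean), as.data.frame(m))
  expect_equal(nrow(avg$sd), 0) # sd identically zero
  expect_equal(avg$n, 3)

  # translated copy with shifted centre aligns back onto the original
  m2 <- shift_map(m, 5, -2)
  avg2 <- align_and_average(list(m, m2), list(c(0, 0), c(5, -2)),
                            window_radius = 3)
  expect_equal(as.data.frame(avg2$mean), as.data.frame(m))

  # scalar mean and population sd
  avg3 <- align_and_average(list(hexel_map(0, 0, 2), hexel_map(0, 0, 4)),
                            list(c(0, 0), c(0, 0)), window_radius = 1)
  expect_equal(map_lookup(avg3$mean, 0, 0), 3)
  expect_equal(map_lookup(avg3$sd, 0, 0), 1)
  expect_error(align_and_average(list(m), list(c(0, 0)), window_radius = 0),
               "window_radius")
})

test_that("align_and_average matches the type-average map formula", {
  # f_AB(r) = (1/|B|) sum_{a,b} delta(r, r_a - r_b) W_ab with centres at r_b
  fx <- random_connectome(n_cells = 40, n_types = 4, seed = 6)
  A <- "T1"; B <- "T2"
  b_cells <- cells_of_type(fx$conn, B)
  asg_b <- fx$assigns[[B]]
  maps <- lapply(b_cells, function(b)
    suppressMessages(mono_map_cell(fx$conn, fx$assigns[[A]], A, b)))
  centres <- lapply(b_cells, function(b) {
    pos <- match(b, asg_b$id)
    c(asg_b$p[pos], asg_b$q[pos])
  })
  avg <- align_and_average(maps, centres, window_radius = 8)
  # direct double loop over the Methods-style definition
  W <- as.matrix(fx$conn$W)
  a_cells <- cells_of_type(fx$conn, A)
  asg_a <- fx$assigns[[A]]
  direct <- list()
  for (a in a_cells) for (b in b_cells) {
    ra <- c(asg_a$p[match(a, asg_a$id)], asg_a$q[match(a, asg_a$id)])
    rb <- c(asg_b$p[match(b, asg_b$id)], asg_b$q[match(b, asg_b$id)])
    key <- paste(ra[1] - rb[1], ra[2] - rb[2])
    direct[[key]] <- (if (is.null(direct[[key]])) 0 else direct[[key]]) +
      W[a, b] / length(b_cells)
  }
  for (key in names(direct)) {
    pq <- as.integer(strsplit(key, " ")[[1]])
    if (hex_dist(0, 0, pq[1], pq[2]) <= 8)
      expect_equal(map_lookup(avg$mean, pq[1], pq[2]), direct[[key]])
  }
})

test_that("maps and centres are translation-equivariant", {
  fx <- bar_fixture()
  shift <- c(4L, -3L)
  asg2 <- lattice_assignment(fx$asg$id, fx$asg$p + shift[1],
                             fx$asg$q + shift[2], type = "Tm1")
  m1 <- mono_map_cell(fx$conn, fx$asg, "Tm1", "t")
  m2 <- mono_map_cell(fx$conn, asg2, "Tm1", "t")
  expect_equal(as.data.frame(shift_map(m1, shift[1], shift[2])),
               as.data.frame(m2))
  expect_equal(centre_of_map(m2), centre_of_map(m1) + shift,
               ignore_attr = TRUE)
})

test_that("reference centre falls back to the disynaptic map for LC-style cells", {
  # target with no direct hexel input, only a disynaptic route
  cells <- data.frame(id = c("s", "mid", "lc"), type = c("Tm1", "X", "LC"))
  ed <- data.frame(pre = c("s", "mid"), post = c("mid", "lc"), count = c(3, 6))
  conn <- connectome(cells, ed)
  asg <- lattice_assignment("s", 2L, 2L, type = "Tm1")
  expect_message(
    ctr_mono <- reference_centre(conn, asg, "Tm1", "lc"),
    "excluded")
  expect_null(ctr_mono)
  ctr_di <- reference_centre(conn, asg, c("Tm1", "X"), "lc")
  expect_equal(ctr_di, c(p = 2, q = 2))
})

test_that("hexel map CSV round-trips with its unit", {
  m <- hexel_map(c(0, 2), c(1, -1), c(0.25, 0.5), unit = "probability")
  f <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(m, f)
  back <- read_map_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(m))
  expect_identical(attr(back, "unit"), "probability")
})
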