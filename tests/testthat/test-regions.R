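test_that("extract_regions finds maximal runs above the length threshold", {
  dis <- paste0("0", strrep("1", 11), "00", strrep("1", 9), "0")
  p <- make_protein("P1", random_seq(nchar(dis)), dis)
  reg <- extract_regions(p, "disorder", min_len = 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 2)
  expect_equal(reg$end, 12)
  expect_equal(reg$length, 11)

  none <- make_protein("P2", random_seq(6), "000000")
  expect_equal(nrow(extract_regions(none, "disorder")), 0)

  # unannotated residues break a run
  brk <- make_protein("P3", random_seq(25), paste0(strrep("1", 12), "-", strrep("1", 12)))
  reg <- extract_regions(brk, "disorder", min_len = 10)
  expect_equal(reg$length, c(12, 12))
})

test_that("region lengths never exceed the positive-residue count; equal at min_len 1", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    tr <- paste(sample(c("0", "1", "-"), n, replace = TRUE, prob = c(.4, .5, .1)),
                collapse = "")
    p <- make_protein("X", random_seq(n), tr)
    npos <- sum(p$disorder == 1L, na.rm = TRUE)
    expect_lte(sum(extract_regions(p, "disorder", min_len = 3)$length), npos)
    expect_equal(sum(extract_regions(p, "disorder", min_len = 1)$length), npos)
  }
})

test_that("disorder content counts all disordered residues over full length", {
  p <- make_protein("P", random_seq(10), "1111100000")
  expect_equal(disorder_content(p), 0.5)
  expect_equal(disorder_content(make_protein("Q", random_seq(4), "0000")), 0)
  # runs shorter than the IDR minimum still count toward content
  q <- make_protein("R", random_seq(20), paste0(strrep("1", 5), strrep("0", 15)))
  expect_equal(disorder_content(q), 0.25)
  expect_equal(nrow(extract_regions(q, "disorder")), 0)
})

test_that("IDR categories follow the length/content/binding rules", {
  # short: length 12 in a protein with content 0.2
  short <- make_protein("S", random_seq(60), paste0(strrep("1", 12), strrep("0", 48)))
  cat_s <- categorize_idrs(list(S = short))
  expect_true(cat_s$short)
  expect_false(cat_s$long || cat_s$fully_disordered || cat_s$binding)

  # long + binding: length 80, content 0.5, overlapping a binding run
  n <- 160
  long <- make_protein("L", random_seq(n),
                       paste0(strrep("1", 80), strrep("0", 80)),
                       paste0(strrep("0", 30), strrep("1", 10), strrep("0", 120)))
  cat_l <- categorize_idrs(list(L = long))
  expect_true(cat_l$long && cat_l$binding)
  expect_false(cat_l$short || cat_l$other)

  # fully disordered protein: every IDR carries the flag
  fd <- make_protein("F", random_seq(50), paste0(strrep("1", 45), strrep("0", 5)))
  expect_true(categorize_idrs(list(F = fd))$fully_disordered)

  # mid-length IDR in a low-content protein matches no size rule -> other
  oth <- make_protein("O", random_seq(200), paste0(strrep("1", 30), strrep("0", 170)))
  expect_true(categorize_idrs(list(O = oth))$other)
})

test_that("category assignment is a pure function of the inputs", {
  set.seed(7)
  prots <- lapply(1:12, function(i) {
    n <- sample(40:120, 1)
    make_protein(paste0("P", i), random_seq(n),
                 paste(sample(c("0", "1"), n, TRUE, prob = c(.6, .4)), collapse = ""))
  })
  names(prots) <- vapply(prots, `[[`, "", "id")
  a <- categorize_idrs(prots)
  b <- categorize_idrs(prots[sample(names(prots))])
  b <- b[order(match(b$protein_id, a$protein_id), b$start), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("protein classes partition the dataset with the stated precedence", {
  mk <- function(id, n, dis, bind = NULL) make_protein(id, random_seq(n), dis, bind)
  prots <- list(
    # content 0.85 -> fully disordered
    C1 = mk("C1", 100, paste0(strrep("1", 85), strrep("0", 15))),
    # content 0.12, one 12-residue IDR -> low_short
    C2 = mk("C2", 100, paste0(strrep("1", 12), strrep("0", 88))),
    # content 0.2, 20-residue binding IDR -> low_binding_long
    C3 = mk("C3", 100, paste0(strrep("1", 20), strrep("0", 80)),
            paste0(strrep("1", 20), strrep("0", 80))),
    # same but non-binding -> low_nonbinding_long
    C4 = mk("C4", 100, paste0(strrep("1", 20), strrep("0", 80))),
    # content 0.5 with binding IDR -> high_binding
    C5 = mk("C5", 100, paste0(strrep("1", 50), strrep("0", 50)),
            paste0(strrep("0", 10), strrep("1", 15), strrep("0", 75))),
    # content 0.5, no binding -> high_nonbinding
    C6 = mk("C6", 100, paste0(strrep("1", 50), strrep("0", 50))),
    # content 0.05, no qualifying IDR -> unassigned
    U1 = mk("U1", 100, paste0(strrep("1", 5), strrep("0", 95))),
    # the literal length-15 gap: neither short (<15) nor long (>15)
    U2 = mk("U2", 100, paste0(strrep("1", 15), strrep("0", 85)))
  )
  cls <- classify_idps(prots)
  expect_equal(cls$class,
               c("fully_disordered", "low_short", "low_binding_long",
                 "low_nonbinding_long", "high_binding", "high_nonbinding",
                 "unassigned", "unassigned"))
  # precedence: a low-content protein with both a short and a binding long IDR
  both <- mk("B", 200, paste0(strrep("1", 12), "0", strrep("1", 20), strrep("0", 167)),
             paste0(strrep("0", 13), strrep("1", 20), strrep("0", 167)))
  expect_equal(classify_idps(list(B = both))$class, "low_binding_long")
  # every protein maps to exactly one label
  expect_true(all(cls$class %in% IDP_CLASSES))
  expect_equal(nrow(cls), length(prots))
})

test_that("region_summary reports counts and length statistics per category", {
  prots <- list(
    A = make_protein("A", random_seq(150),
                     paste0(strrep("1", 10), "0", strrep("1", 12), "0",
                            strrep("1", 14), strrep("0", 112))),
    B = make_protein("B", random_seq(30), strrep("0", 30))
  )
  s <- region_summary(prots)
  short_row <- s[s$set == "short", ]
  expect_equal(short_row$n_regions, 3)
  expect_equal(short_row$median_length, 12)
  expect_equal(short_row$mean_length, 12.0)
  expect_equal(s[s$set == "complete", ]$n_residues, 36)

  empty <- region_summary(list())
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)
})
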