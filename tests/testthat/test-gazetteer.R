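test_that("gazetteer files parse patterns, comments and directives", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "", "suicid* ideat*"), f)
  g <- read_gazetteer(f)
  expect_length(g$entries, 1L)
  expect_equal(g$entries[[1]], c("suicid*", "ideat*"))
  expect_equal(g$case_policy, "fold")

  f2 <- withr::local_tempfile()
  writeLines(c("# only", "", "# comments"), f2)
  expect_length(read_gazetteer(f2)$entries, 0L)

  f3 <- withr::local_tempfile()
  writeLines("attempt to end her life", f3)
  expect_equal(read_gazetteer(f3)$entries[[1]],
               c("attempt", "to", "end", "her", "life"))

  f4 <- withr::local_tempfile()
  writeLines("*", f4)
  expect_error(read_gazetteer(f4), "lone '\\*'")

  f5 <- withr::local_tempfile()
  writeLines(c("#!case: exact", "Suicide"), f5)
  expect_equal(read_gazetteer(f5)$case_policy, "exact")
})

test_that("wildcard matching is prefix-based per token", {
  g <- gazetteer(list("ideat*"))
  expect_equal(match_gazetteer(g, c("idea", "ideation", "ideations"))$first,
               c(2L, 3L))
  g2 <- gazetteer(list("suicid* ideat*"))
  m <- match_gazetteer(g2, c("ongoing", "suicidal", "ideation"))
  expect_equal(m[, c("first", "last")], data.frame(first = 2L, last = 3L))
  g3 <- gazetteer(list("attempt*"))
  m3 <- match_gazetteer(g3, c("No", "attempts", "made"))
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$first, 2L)
})

test_that("case policy controls folding and apostrophes align with the tokenizer", {
  ge <- gazetteer(list("Suicide"), case_policy = "exact")
  expect_equal(nrow(match_gazetteer(ge, c("suicide"))), 0L)
  expect_equal(nrow(match_gazetteer(ge, c("Suicide"))), 1L)
  gf <- gazetteer(list("didn't"))
  expect_equal(gf$entries[[1]], c("didn", "'", "t"))
  toks <- tokenize("she didn't attend")$surface
  expect_equal(nrow(match_gazetteer(gf, toks)), 1L)
})

test_that("matcher agrees with a regex oracle on random pattern/sentence pairs", {
  set.seed(99)
  alphabet <- c("ab", "abc", "abcd", "xy", "xyz", "qrs", "a", "b", "q", "x")
  esc <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
  for (i in 1:1000) {
    np <- sample(1:3, 1)
    pat <- sample(alphabet, np, replace = TRUE)
    wild <- runif(np) < 0.5
    pat_str <- ifelse(wild, paste0(pat, "*"), pat)
    toks <- sample(alphabet, sample(3:10, 1), replace = TRUE)
    got <- match_gazetteer(gazetteer(list(pat_str)), toks)

    # oracle: regex over the space-joined sentence, token offsets recovered
    # from character positions; the body sits inside a lookahead so that
    # overlapping occurrences are all found
    sent <- paste(toks, collapse = " ")
    rx <- paste0("(?<=^| )(?=",
                 paste(ifelse(wild, paste0(esc(pat), "[a-z]*"), esc(pat)),
                       collapse = " "),
                 "( |$))")
    m <- gregexpr(rx, sent, perl = TRUE)[[1]]
    tok_start <- cumsum(c(1, head(nchar(toks), -1) + 1))
    exp_first <- if (m[1] == -1) integer(0) else match(as.integer(m), tok_start)
    expect_equal(sort(got$first), sort(exp_first),
                 info = paste("pattern:", paste(pat_str, collapse = " "),
                              "sentence:", sent))
    if (nrow(got)) expect_equal(got$last - got$first + 1L, rep(np, nrow(got)))
  }
})
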