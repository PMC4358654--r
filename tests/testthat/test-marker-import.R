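test_that("marker lists parse with default and custom separators", {
  expect_equal(unname(read_marker_list(text = "0,0,0\n1,0,0")),
               rbind(c(0, 0, 0), c(1, 0, 0)))
  # semicolon delimiter with decimal comma: the documented substitution rule
  got <- read_marker_list(text = "1,5;2,5;3,75",
                          options = u3d_read_options(delimiter = ";",
                                                     decimal_separator = ","))
  expect_equal(unname(got), matrix(c(1.5, 2.5, 3.75), 1))
  # fields beyond x,y,z (labels, timestamps) are ignored
  got <- read_marker_list(text = "1,2,3,label,9")
  expect_equal(unname(got), matrix(c(1, 2, 3), 1))
  # whitespace-run delimiting
  got <- read_marker_list(text = "  1\t 2   3 ",
                          options = u3d_read_options(delimiter = " "))
  expect_equal(unname(got), matrix(c(1, 2, 3), 1))
})

test_that("decimal-comma parsing equals dot parsing of the rewritten file", {
  set.seed(5)
  vals <- matrix(round(runif(60, -10, 10), 4), ncol = 3)
  dot_text <- apply(vals, 1, function(r) paste(sprintf("%g", r), collapse = ";"))
  comma_text <- gsub(".", ",", dot_text, fixed = TRUE)
  a <- read_marker_list(text = comma_text,
                        options = u3d_read_options(delimiter = ";",
                                                   decimal_separator = ","))
  b <- read_marker_list(text = dot_text,
                        options = u3d_read_options(delimiter = ";"))
  expect_identical(a, b)
  expect_equal(unname(a), vals)
})

test_that("comments, blank lines and malformed rows are handled", {
  txt <- c("# a comment", "", "0,0,0", "   ", "# another", "1,1,1")
  expect_equal(nrow(read_marker_list(text = txt)), 2)
  expect_error(read_marker_list(text = "1,2"), "row 1.*expected at least 3")
  expect_error(read_marker_list(text = c("0,0,0", "1,x,3")),
               "row 2, column 2: 'x' is not numeric")
  expect_error(u3d_read_options(delimiter = ",", decimal_separator = ","),
               "must differ")
})

test_that("row filters agree with a brute-force scan on random tables", {
  set.seed(77)
  for (case in 1:60) {
    n <- sample(0:40, 1)
    rows <- replicate(n, paste(c(sprintf("%g", runif(3)),
                                 sample(c("a", "b"), 1)), collapse = ","))
    start <- sample(0:5, 1)
    stride <- sample(1:4, 1)
    max_rows <- if (runif(1) < 0.5) sample(1:10, 1)
    use_match <- runif(1) < 0.4
    match_keep <- if (use_match && n > 0)
      vapply(rows, function(r) strsplit(r, ",")[[1]][4] == "a", logical(1))
    else rep(TRUE, n)
    flt <- u3d_row_filter(start_row = start, stride = stride,
                          max_rows = max_rows,
                          match_column = if (use_match) 3L,
                          match_value = if (use_match) "a")
    got <- read_marker_list(text = rows,
                            options = u3d_read_options(filter = flt))
    expect_identical(nrow(got),
                     oracle_filter_count(n, start, stride, max_rows,
                                         match_keep))
  }
  # the spec'd arithmetic case: 100 rows, stride 2 -> 50 positions
  rows <- sprintf("%d,0,0", 1:100)
  flt <- u3d_row_filter(stride = 2)
  expect_identical(nrow(read_marker_list(text = rows,
                                         options = u3d_read_options(filter = flt))),
                   50L)
})

test_that("connection lists read 0-based pairs into 1-based edges", {
  expect_equal(unname(read_connections(text = c("0,1", "1,2"))),
               rbind(c(1L, 2L), c(2L, 3L)))
  expect_identical(nrow(read_connections(text = character(0))), 0L)
  expect_error(read_connections(text = "0"), "expected at least 2")
  expect_error(read_connections(text = "0,-1"), "non-negative integer")
  expect_error(read_connections(text = "0,1.5"), "non-negative integer")
})

test_that("auto_connect builds the n-1 chain", {
  expect_equal(unname(auto_connect(5)), cbind(1:4, 2:5))
  expect_identical(nrow(auto_connect(1)), 0L)
  expect_identical(nrow(auto_connect(0)), 0L)
  for (n in c(0L, 1L, 2L, 5L, 100L))
    expect_identical(nrow(auto_connect(n)), max(n - 1L, 0L))
})
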