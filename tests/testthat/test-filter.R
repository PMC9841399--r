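num_types <- c(a = "num", b = "num", c = "num", x = "num", y = "num", z = "num",
               gnomad_popmax_af = "num", gnomad_popmax_nhomalt = "num",
               gnomad_popmax_an = "num", csq = "str")

test_that("field-name threshold, ratio and OR expressions parse and evaluate", {
  f1 <- parse_filter("gnomad_popmax_af < 0.01", num_types)
  expect_identical(f1$ast$kind, "binary")
  expect_identical(f1$ast$op, "<")
  expect_true(eval_filter(f1, list(gnomad_popmax_af = 0.005)))
  expect_false(eval_filter(f1, list(gnomad_popmax_af = 0.05)))

  f2 <- parse_filter("gnomad_popmax_nhomalt / (gnomad_popmax_an / 2) < 0.005",
                     num_types)
  # 10 / (10000/2) = 0.002 < 0.005
  expect_true(eval_filter(f2, list(gnomad_popmax_nhomalt = 10,
                                   gnomad_popmax_an = 10000)))
  expect_false(eval_filter(f2, list(gnomad_popmax_nhomalt = 100,
                                    gnomad_popmax_an = 10000)))

  f3 <- parse_filter("x > 0.2 || y > 0.2 || z > 0.2", num_types)
  expect_false(eval_filter(f3, list(x = 0.1, y = 0.1, z = 0.1)))
  expect_true(eval_filter(f3, list(x = 0.1, y = 0.3, z = 0.1)))
})

test_that("string fields support equality against quoted literals only", {
  f <- parse_filter("csq == 'missense' || csq == \"stop_gained\"", num_types)
  expect_true(eval_filter(f, list(csq = "missense")))
  expect_false(eval_filter(f, list(csq = "intron")))
  expect_error(parse_filter("csq + 1 > 0", num_types), "arithmetic")
  expect_error(parse_filter("csq < 'a'", num_types), "numeric operands")
  expect_error(parse_filter("csq == 1", num_types), "mismatched")
})

test_that("malformed or ill-typed expressions fail with positions, before evaluation", {
  expect_error(parse_filter("a <", num_types), "syntax error")
  expect_error(parse_filter("", num_types), "empty")
  expect_error(parse_filter("a ? b", num_types), "position 3")
  expect_error(parse_filter("(a < 1", num_types), "expected '\\)'")
  expect_error(parse_filter("unknown_field < 1", num_types), "unknown field")
  expect_error(parse_filter("a + 1", num_types), "boolean-typed")   # numeric root
  expect_error(parse_filter("a && b", num_types), "boolean operands")
})

test_that("evaluator agrees with base R on random expressions and environments", {
  set.seed(17)
  vars <- c("a", "b", "c")
  # random comparison leaves over +,-,* arithmetic (division excluded here:
  # its zero-divisor semantics deliberately differ from base R), combined
  # with &&, || and !
  rand_arith <- function(depth) {
    if (depth <= 0 || runif(1) < 0.4) {
      if (runif(1) < 0.5) sample(vars, 1) else format(round(runif(1, -5, 5), 2))
    } else {
      sprintf("(%s %s %s)", rand_arith(depth - 1), sample(c("+", "-", "*"), 1),
              rand_arith(depth - 1))
    }
  }
  rand_bool <- function(depth) {
    if (depth <= 0 || runif(1) < 0.4) {
      sprintf("%s %s %s", rand_arith(1), sample(c("<", "<=", ">", ">=", "==", "!="), 1),
              rand_arith(1))
    } else if (runif(1) < 0.25) {
      sprintf("!(%s)", rand_bool(depth - 1))
    } else {
      sprintf("(%s) %s (%s)", rand_bool(depth - 1), sample(c("&&", "||"), 1),
              rand_bool(depth - 1))
    }
  }
  for (i in 1:300) {
    txt <- rand_bool(3)
    env <- list(a = round(runif(1, -5, 5), 2), b = round(runif(1, -5, 5), 2),
                c = round(runif(1, -5, 5), 2))
    mine <- eval_filter(parse_filter(txt, num_types), env)
    ref <- eval(parse(text = txt)[[1]], envir = env)
    expect_identical(mine, ref, label = txt)
  }
})

test_that("|| and && short-circuit (poisoned-division probe)", {
  f <- parse_filter("a > 0 || 1 / (a - a) > 0", num_types)
  # left true: the zero division on the right must never run
  expect_true(eval_filter(f, list(a = 1)))
  # left false: the right side's division by zero fails the record
  expect_warning(res <- filter_passes(f, list(a = -1),
                                      warn_once = new.env()), "division by zero")
  expect_false(res)
  g <- parse_filter("a < 0 && 1 / (a - a) > 0", num_types)
  expect_false(eval_filter(g, list(a = 1)))  # left false short-circuits &&
})

test_that("division-by-zero warning is emitted only once across records", {
  f <- parse_filter("1 / a > 0", num_types)
  warn_env <- new.env()
  expect_warning(filter_passes(f, list(a = 0), warn_once = warn_env))
  expect_no_warning(filter_passes(f, list(a = 0), warn_once = warn_env))
})

test_that("De Morgan holds for random boolean sub-expressions", {
  set.seed(23)
  for (i in 1:100) {
    lhs <- sprintf("a %s %s", sample(c("<", ">", "<=", ">="), 1),
                   format(round(runif(1, -2, 2), 2)))
    rhs <- sprintf("b %s %s", sample(c("<", ">", "<=", ">="), 1),
                   format(round(runif(1, -2, 2), 2)))
    env <- list(a = round(runif(1, -2, 2), 2), b = round(runif(1, -2, 2), 2))
    neg <- eval_filter(parse_filter(sprintf("!((%s) && (%s))", lhs, rhs), num_types), env)
    dis <- eval_filter(parse_filter(sprintf("!(%s) || !(%s)", lhs, rhs), num_types), env)
    expect_identical(neg, dis)
  }
})

test_that("precedence follows the conventional ladder", {
  t <- c(a = "num", b = "num", c = "num")
  expect_true(eval_filter(parse_filter("a + b * c == 7", t), list(a = 1, b = 2, c = 3)))
  expect_true(eval_filter(parse_filter("a - b - c == -4", t), list(a = 1, b = 2, c = 3)))
  expect_true(eval_filter(parse_filter("a / (b / 2) < 0.005", t),
                          list(a = 1, b = 500, c = 0)))
  expect_true(eval_filter(parse_filter("-a < 0", t), list(a = 2, b = 0, c = 0)))
  # && binds tighter than ||
  f <- parse_filter("a > 0 || b > 0 && c > 0", t)
  expect_true(eval_filter(f, list(a = 1, b = -1, c = -1)))
  expect_false(eval_filter(f, list(a = -1, b = 1, c = -1)))
})
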