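#' Summarize per-view root counts into visibility bins
#'
#' Bins each of the eight side views by its visible root count: `a` views
#' show at least 3 roots, `b` views show exactly 2, `c` views show 0 or 1.
#' These three tallies (always summing to 8) are the inputs of the root
#' grading standard.
#'
#' @param counts Integer vector of length 8, visible roots per side view
#'   in angle order.
#' @return An object of class `root_view_summary`: list with fields `a`,
#'   `b`, `c`.
#' @export
summarize_views <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 8L || anyNA(counts) || any(counts < 0))
    stop("`counts` must be 8 nonnegative per-view root counts")
  structure(list(a = sum(counts >= 3L), b = sum(counts == 2L),
                 c = sum(counts <= 1L)),
            class = "root_view_summary")
}

root_view_summary <- function(a, b, c) {
  a <- as.integer(a); b <- as.integer(b); c <- as.integer(c)
  if (any(c(a, b, c) < 0) || a + b + c != 8L)
    stop("a, b, c must be nonnegative and sum to 8")
  structure(list(a = a, b = b, c = c), class = "root_view_summary")
}

#' The commercial root grading standard as data
#'
#' The rule set mapping a [summarize_views()] triple to a root grade
#' (3 best, 1 worst). Each rule is a list with a `grade` and named
#' conditions on `a`, `b`, `c` written as comparator strings (`"==8"`,
#' `"<=6"`, `">=2"`); omitted fields are unconstrained. Rules are
#' evaluated in severity order (all grade-3 rules, then grade-2, then
#' grade-1); triples matched by no rule fall to a documented fallback
#' (`c >= 2` gives grade 1, otherwise `a >= 5` gives grade 2, otherwise
#' grade 1) and are flagged as such so they can be audited.
#'
#' Rule sets are plain data and can be loaded from YAML/JSON via
#' [root_rules_from_yaml()] so nurseries can substitute their own
#' standards.
#'
#' @return List of rules in precedence order.
#' @export
default_root_rules <- function() {
  rule <- function(grade, ...) list(grade = grade, when = list(...))
  list(
    rule(3L, a = "==8"),
    rule(3L, a = "==7", b = "==1"),
    rule(2L, a = "==7", c = "==1"),
    rule(2L, a = "==6", b = "==1", c = "==1"),
    rule(2L, a = "<=6", b = ">=2", c = "==0"),
    rule(1L, a = "<=6", c = ">=2"),
    rule(1L, a = "==4", b = "==2", c = "==2"),
    rule(1L, a = "<=4", b = ">=2", c = ">=2")
  )
}

parse_condition <- function(txt) {
  m <- regmatches(txt, regexec("^(==|<=|>=)\\s*([0-8])$", trimws(txt)))[[1]]
  if (length(m) != 3L) stop("cannot parse rule condition '", txt, "'")
  list(op = m[2], value = as.integer(m[3]))
}

condition_holds <- function(value, cond) {
  cond <- parse_condition(cond)
  switch(cond$op,
         "==" = value == cond$value,
         "<=" = value <= cond$value,
         ">=" = value >= cond$value)
}

rule_matches <- function(s, rule) {
  all(vapply(names(rule$when), function(f) {
    condition_holds(s[[f]], rule$when[[f]])
  }, logical(1)))
}

#' Grade a root system from its view summary
#'
#' Applies the rule set to an `(a, b, c)` summary. The result carries
#' provenance: which rule fired, or whether the fallback was used (the
#' printed standard does not cover every triple, e.g. `a = 5, b = 2,
#' c = 1`).
#'
#' @param s A `root_view_summary` (from [summarize_views()]) or a list
#'   with fields `a`, `b`, `c`.
#' @param rules Rule set, see [default_root_rules()].
#' @return Integer grade in `1:3` with attributes `source` (a rule label
#'   such as `"rule-2.1"` or `"fallback"`) and `fallback` (logical).
#' @export
rule_grade <- function(s, rules = default_root_rules()) {
  if (!inherits(s, "root_view_summary")) s <- root_view_summary(s$a, s$b, s$c)
  counter <- integer(4)
  for (r in rules) {
    counter[r$grade] <- counter[r$grade] + 1L
    if (rule_matches(s, r)) {
      return(structure(r$grade,
                       source = sprintf("rule-%d.%d", r$grade, counter[r$grade]),
                       fallback = FALSE))
    }
  }
  grade <- if (s$c >= 2L) 1L else if (s$a >= 5L) 2L else 1L
  structure(grade, source = "fallback", fallback = TRUE)
}

#' Exhaustive audit of the root grading standard
#'
#' Enumerates all 45 `(a, b, c)` triples with `a + b + c = 8` and grades
#' each, marking which came from a printed rule and which from the
#' fallback. Useful both as documentation of the total mapping and for
#' auditing locally customised rule sets.
#'
#' @param rules Rule set, see [default_root_rules()].
#' @return `data.frame` with columns `a`, `b`, `c`, `grade`, `source`,
#'   `fallback` (45 rows).
#' @export
enumerate_rule_table <- function(rules = default_root_rules()) {
  rows <- do.call(rbind, lapply(0:8, function(a) {
    do.call(rbind, lapply(0:(8 - a), function(b) {
      g <- rule_grade(root_view_summary(a, b, 8L - a - b), rules)
      data.frame(a = a, b = b, c = 8L - a - b, grade = as.integer(g),
                 source = attr(g, "source"), fallback = attr(g, "fallback"))
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Load / save a root rule set as YAML
#'
#' Serialization of the rule standard: a YAML list of mappings, each with
#' a `grade` and a `when` mapping of `a`/`b`/`c` comparator strings.
#'
#' @param path YAML file.
#' @param rules Rule set to write.
#' @return For the reader, a rule set list; for the writer, `path`
#'   invisibly.
#' @export
root_rules_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    if (is.null(r$grade) || !r$grade %in% 1:3)
      stop("each rule needs a grade in 1:3")
    when <- lapply(r$when, as.character)
    if (!all(names(when) %in% c("a", "b", "c")))
      stop("rule conditions must be on a, b, c")
    lapply(when, parse_condition)  # validate early
    list(grade = as.integer(r$grade), when = when)
  })
}

#' @rdname root_rules_from_yaml
#' @export
root_rules_to_yaml <- function(rules, path) {
  yaml::write_yaml(lapply(rules, function(r)
    list(grade = r$grade, when = r$when)), path)
  invisible(path)
}
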