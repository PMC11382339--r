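# shared helpers: random oligo construction under a fixed seed

random_oligo <- function(n, registry = default_registry(),
                         codes = c("A", "C", "G", "T", "mC", "lA", "lG",
                                   "eC", "eT")) {
  toks <- sample(codes, n, replace = TRUE)
  links <- sample(c("*", "."), n - 1, replace = TRUE, prob = c(0.8, 0.2))
  parse_oligo(paste0(toks, c(links, ""), collapse = ""), registry)
}

# direct span summation: the independent oracle for internal fragments.
# Builds the J(L,R) composition from the retained monomers i+1..j plus the
# end-chemistry deltas, never via the subtraction identity.
direct_internal <- function(o, i, j, pair = c("aw", "bx", "cy", "dz")) {
  pair <- match.arg(pair)
  water <- parse_ef("H2O")
  span <- seq.int(i + 1L, j)
  f <- Reduce(`+`, lapply(o$monomers[span], `[[`, "nucleoside"), ef())
  if (length(span) > 1) {
    for (lk in o$linkages[seq.int(i + 1L, j - 1L)])
      f <- f + linkage_formula(lk)
    f <- ef_combine(f, ef(H = 2L * (length(span) - 1L),
                          O = length(span) - 1L), -1L)
  }
  # 5' end: w/x keep the cleaved linkage i phosphate, y/z do not;
  # 3' end: c/d keep linkage j, a/b do not; a/x/z carry an extra -H2O.
  switch(pair,
    aw = f + linkage_formula(o$linkages[i]) - water,
    bx = f + linkage_formula(o$linkages[i]) - water,
    cy = f + linkage_formula(o$linkages[j]) - water,
    dz = f + linkage_formula(o$linkages[j]) - water)
}

expect_ef_equal <- function(a, b) {
  expect_true(isTRUE(all.equal(ef_combine(a, b, -1L), ef())),
              label = paste(ef_string(a), "==", ef_string(b)))
}
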