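# Shared fixtures, all built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_pair <- function(...) build_toy_model(toy_scenario(...))

# A linear conversion chain EX -> M1 -> ... -> Mk -> SINK with random
# upper bounds. Throughput is governed by the tightest bound, which gives
# a closed-form FBA optimum independent of the LP machinery.
random_chain_network <- function(k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- paste0("M", seq_len(k))
  rxn <- c("EX", paste0("R", seq_len(k - 1)), "SINK")
  S <- Matrix::Matrix(0, k, k + 1, sparse = TRUE,
                      dimnames = list(species, rxn))
  S[1, 1] <- 1
  for (j in seq_len(k - 1)) {
    S[j, j + 1] <- -1
    S[j + 1, j + 1] <- 1
  }
  S[k, k + 1] <- -1
  ub <- stats::runif(k + 1, 0.2, 2)
  obj <- c(numeric(k), 1)
  metabolic_network(S, lb = 0, ub = ub, objective = obj)
}

# Independent LP oracle: scipy.optimize.linprog (HiGHS) through the
# system python. Takes a list of instances (obj, A, rhs, lb, ub) and
# returns a data.frame of statuses and optimal values.
scipy_linprog_oracle <- function(cases) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  enc <- lapply(cases, function(cc) list(
    obj = cc$obj, A = cc$A,
    rhs = cc$rhs,
    lb = ifelse(is.finite(cc$lb), cc$lb, NA),
    ub = ifelse(is.finite(cc$ub), cc$ub, NA)))
  jsonlite::write_json(enc, infile, digits = NA, na = "null")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "cases = json.load(open(sys.argv[1]))",
    "out = []",
    "for c in cases:",
    "    rhs = np.array(c['rhs'], dtype=float)",
    "    A = np.array(c['A'], dtype=float).reshape(len(rhs), -1)",
    "    lb = [(-np.inf if v is None else v) for v in c['lb']]",
    "    ub = [(np.inf if v is None else v) for v in c['ub']]",
    "    r = linprog(-np.array(c['obj'], dtype=float), A_eq=A, b_eq=rhs,",
    "                bounds=list(zip(lb, ub)), method='highs')",
    "    st = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(r.status, 'other')",
    "    out.append({'status': st,",
    "                'objective': (-r.fun if st == 'optimal' else None)})",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  rc <- system2("python", c(script, infile, outfile),
                stdout = FALSE, stderr = FALSE)
  if (rc != 0L) stop("python oracle call failed")
  res <- jsonlite::read_json(outfile)
  data.frame(
    status = vapply(res, `[[`, character(1), "status"),
    objective = vapply(res, function(r)
      if (is.null(r$objective)) NA_real_ else r$objective, numeric(1)))
}

expect_network_equal <- function(a, b) {
  expect_identical(a$species_ids, b$species_ids)
  expect_identical(a$reaction_ids, b$reaction_ids)
  expect_equal(as.matrix(a$stoich), as.matrix(b$stoich))
  expect_equal(a$lb, b$lb)
  expect_equal(a$ub, b$ub)
  expect_equal(a$objective_coeffs, b$objective_coeffs)
}
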