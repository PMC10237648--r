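# shared finite-difference and fixture helpers

fd_gradient <- function(f, x, indices = seq_along(x), h = 1e-5) {
  vapply(indices, function(k) {
    e <- numeric(length(x))
    e[k] <- h * max(1, abs(x[k]))
    (f(x + e) - f(x - e)) / (2 * e[k])
  }, numeric(1L))
}

max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}

table1_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("ID,Time,Value",
               "1,1.5,11.00",
               "2,1.5,8.30",
               "1,2.1,11.52",
               "3,2.1,9.80",
               "1,4,12.03",
               "2,4,8.50"), path)
  path
}

cancer_fixture <- function(m = 1L, seed = 42L) generate_cancer(m, seed = seed)
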