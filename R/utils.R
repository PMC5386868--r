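# internal helpers shared across modules

# Haldane map function: genetic distance (cM) <-> recombination fraction
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

haldane_d <- function(r) {
  r <- pmin(pmax(r, 0), 0.4999999)
  -50 * log(1 - 2 * r)
}

# Derive a stage-specific child seed from a master seed; keeps all streams
# reproducible from one integer while decoupling stages from each other.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.double(abs(as.integer(master)) %% 2147483647)
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# negative-binomial depth draw; dispersion phi parameterizes var = mu(1+phi),
# phi = 0 means deterministic (no sampling noise)
rdepth <- function(n, mu, dispersion) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (dispersion == 0) return(rep(mu, n))
  stats::rnbinom(n, mu = mu, size = mu / dispersion)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
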