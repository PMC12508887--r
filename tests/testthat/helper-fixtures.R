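# Shared fixtures, built once per test run.

# the default bacteriocyte phantom under study conditions (48 x 48,
# SNR 20, baseline + gain + spikes), plus its preprocessed cube
.ph <- makeCellPhantom(seed = 7)
.phPre <- runPreprocess(.ph$cube, preprocessConfig())$cube

# a small clean phantom for fast exact checks
.phClean <- makeCellPhantom(width = 24, height = 24, snr = Inf,
                            baseline = FALSE, nSpikes = 0, gain = FALSE,
                            seed = 3)

libraryWindows <- function() {
  lib <- libraryEntries(defaultLibrary())
  out <- lapply(names(lib), function(nm) {
    w <- lib[[nm]]$windows[[1]]
    w@label <- nm
    w
  })
  names(out) <- names(lib)
  out
}

# flat toy cube: constant spectrum everywhere (optionally + noise)
toyCube <- function(width = 4, height = 4, nchan = 32, value = 1,
                    noise = 0, seed = 1) {
  set.seed(seed)
  ax <- seq(400, 400 + 2 * (nchan - 1), by = 2)
  S <- matrix(value, width * height, nchan) +
    matrix(rnorm(width * height * nchan, sd = noise), width * height)
  RamanCube(S, ax, width, height)
}

# best-match permutation between true and estimated endmember sets,
# by total cosine similarity (exhaustive over k! for small k)
bestPermutation <- function(E, Eh) {
  k <- nrow(E)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- if (k == 1) matrix(1) else
    as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  scores <- apply(perms, 1, function(p)
    sum(vapply(seq_len(k), function(i) cosv(E[i, ], Eh[p[i], ]),
               numeric(1))))
  perms[which.max(scores), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
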