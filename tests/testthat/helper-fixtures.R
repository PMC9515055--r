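# Shared fixtures, all generated in code.

.fixture_env <- new.env(parent = emptyenv())

# memoised mini synthetic dataset (8 volumes of 32 x 32 x 64)
mini_dataset <- function() {
  if (is.null(.fixture_env$mini)) {
    dir <- file.path(tempdir(), "bonebem-mini")
    .fixture_env$mini <- generateDataset(
      dir, nVolumes = 4L, split = c(train = 2L, val = 0L, test = 2L),
      seed = 11L, params = anatomyParams(volumeShape = c(32L, 32L, 64L)))
  }
  .fixture_env$mini
}

# a random label volume plus a loosely matching CT
random_volume_pair <- function(seed, shape = c(20L, 20L, 20L),
                               nClasses = 5L) {
  set.seed(seed)
  lab <- array(sample(0:(nClasses - 1L), prod(shape), replace = TRUE,
                      prob = c(0.7, rep(0.3 / (nClasses - 1), nClasses - 1))),
               shape)
  labv <- LabelVolume(lab, nClasses = nClasses)
  ct <- array(stats::rnorm(prod(shape), mean = ifelse(lab > 0, 500, -200),
                           sd = 50), shape)
  list(ct = CTVolume(ct), labels = labv)
}

# normalised random probability volume
random_prob_volume <- function(seed, shape = c(8L, 8L, 8L), N = 4L) {
  set.seed(seed)
  p <- array(stats::runif(prod(shape) * N), c(shape, N))
  s <- array(rep(rowSums(matrix(p, ncol = N)), times = N), c(shape, N))
  ProbabilityVolume(p / s)
}

tiny_config <- function(variant = "baseline", C = 5L)
  networkConfig(variant, nClassesMulti = C, levels = 2L,
                channels = c(4L, 8L))

# independent closed-form parameter count for the shipped architecture
expected_param_count <- function(variant, C, channels) {
  conv3 <- function(a, b) 27 * a * b + b
  conv1 <- function(a, b) a * b + b
  innorm <- function(b) 2 * b
  unit <- function(a, b) conv3(a, b) + innorm(b)
  block <- function(a, b) unit(a, b) + unit(b, b)
  L <- length(channels)
  enc <- block(1, channels[1])
  for (l in 2:L) enc <- enc + block(channels[l - 1], channels[l])
  dec <- 0
  for (l in seq(L - 1, 1))
    dec <- dec + block(channels[l + 1] + channels[l], channels[l])
  total <- enc + dec + conv1(channels[1], C)
  extra <- switch(variant,
    baseline = 0,
    dual_a = conv1(channels[1], 2),
    dual_b = 2 * unit(channels[1], channels[1]) + conv1(channels[1], 2),
    dual_c = unit(channels[1], channels[1]) + conv1(channels[1], 2),
    dual_d = dec + conv1(channels[1], 2))
  total + extra
}

# flood-fill connected components oracle (pure R BFS)
bfs_components <- function(arr, connectivity = 26L) {
  dm <- dim(arr)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  comp <- array(0L, dm)
  k <- 0L
  for (i in which(arr != 0L)) {
    if (comp[i] != 0L) next
    k <- k + 1L
    queue <- i
    comp[i] <- k
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      vz <- (v - 1L) %/% (dm[1] * dm[2])
      vy <- ((v - 1L) %% (dm[1] * dm[2])) %/% dm[1]
      vx <- (v - 1L) %% dm[1]
      for (o in seq_len(nrow(off))) {
        nx <- vx + off[o, 1]; ny <- vy + off[o, 2]; nz <- vz + off[o, 3]
        if (nx < 0 || nx >= dm[1] || ny < 0 || ny >= dm[2] ||
            nz < 0 || nz >= dm[3]) next
        u <- 1L + nx + dm[1] * (ny + dm[2] * nz)
        if (comp[u] == 0L && arr[u] == arr[v]) {
          comp[u] <- k
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}
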