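# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# Derive a reproducible child seed (< 2^31) from a master seed and a
# stream label, so independent stages of one run draw from independent
# but fully determined streams.
child_seed <- function(seed, stream) {
  s <- utf8ToInt(as.character(stream))
  h <- sum(s * seq_along(s)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h + 1) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Draw from an exponential mixture: weights w (sum 1), time constants tau.
# The drawn component index is attached as attribute "component".
rexp_mixture <- function(n, w, tau) {
  if (n == 0L) {
    out <- numeric(0)
    attr(out, "component") <- integer(0)
    return(out)
  }
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- stats::rexp(n, rate = 1 / tau[comp])
  attr(out, "component") <- comp
  out
}

# Uniform points inside an axis-aligned ellipse centered at `center`.
runif_ellipse <- function(n, semiaxes, center = c(0, 0)) {
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = center[1] + semiaxes[1] * r * cos(th),
        y = center[2] + semiaxes[2] * r * sin(th))
}

CHANNELS <- c("pold", "pcna")

check_channel <- function(channel) {
  if (!all(channel %in% CHANNELS))
    stopf("channel must be one of: %s", paste(CHANNELS, collapse = ", "))
  channel
}

# Frame-time convention for the alternating two-channel acquisition:
# the 'pcna' channel is exposed at t = k * dt, the 'pold' channel half a
# frame later at t = k * dt + dt / 2 (k is the 0-based per-channel frame).
channel_offset <- function(channel, frame_interval) {
  ifelse(channel == "pold", frame_interval / 2, 0)
}

frame_times <- function(frames, channel, frame_interval) {
  frames * frame_interval + channel_offset(channel, frame_interval)
}
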