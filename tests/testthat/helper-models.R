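# shared fixture builders (everything is generated in code)

# constant-coefficient model, optionally without cross competition/impulses
const_model <- function(a10 = 1, a11 = 0.35, c1 = 0.3, a12 = 0, m1 = 2,
                        delays = rep(0, 6), schedule = NULL) {
  if (is.null(schedule))
    schedule <- impulse_schedule(numeric(0), h = matrix(numeric(0), 0, 2))
  names(delays) <- c("tau10", "tau11", "tau12", "tau20", "tau21", "tau22")
  schoener_model(a10 = a10, a20 = a10, a11 = a11, a22 = a11,
                 a12 = a12, a21 = a12, m1 = m1, m2 = m1, c1 = c1, c2 = c1,
                 delays = delays, schedule = schedule)
}

# single-species schedule with constant h
sched1 <- function(points, h) impulse_schedule(points, h)

# two-species schedule with constant h pair
sched2 <- function(points, h1, h2)
  impulse_schedule(points, cbind(rep(h1, length(points)),
                                 rep(h2, length(points))))

# brute-force check of the counting inequality i(s,t) <= A(t-s) + A over an
# exhaustive family of open windows (tightest windows around every index
# pair, plus a sliding scan)
counting_ok <- function(points, A, horizon = range(points), eps = 1e-9) {
  if (length(points) == 0L) return(TRUE)
  for (i in seq_along(points)) for (j in i:length(points)) {
    s <- points[i] - eps; t <- points[j] + eps
    cnt <- sum(points > s & points < t)
    if (cnt > A * (t - s) + A) return(FALSE)
  }
  for (len in c(0.1, 0.5, 1, 2, 7.3)) {
    for (s in seq(horizon[1] - len, horizon[2], by = len / 3)) {
      cnt <- sum(points > s & points < s + len)
      if (cnt > A * len + A) return(FALSE)
    }
  }
  TRUE
}
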