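# Fixtures are built in code: axis-aligned rectangle vertebrae in image
# coordinates (x right, y down; superior corners have smaller y), plus
# helpers to transform whole exams.

rectVertebra <- function(level, x0 = 0, y0 = 0, w = 15, h = 11) {
  vertebraLandmarks(level, rbind(
    AS = c(x0 + w, y0),
    AI = c(x0 + w, y0 + h),
    PS = c(x0, y0),
    PI = c(x0, y0 + h)))
}

# two-vertebra exam (C4 above C5), parallel endplates, disc gap `gap`,
# optional anterior slide of C4 in flexion
twoVertebraExam <- function(gap = 3, slide_flex = 0, w = 15, h = 11,
                            exam_id = "fix") {
  c5 <- rectVertebra("C5", 0, 0, w, h)
  c4f <- rectVertebra("C4", slide_flex, -(gap + h), w, h)
  c4e <- rectVertebra("C4", 0, -(gap + h), w, h)
  examLandmarks(exam_id,
                radiographLandmarks("flexion", list(c4f, c5), "right"),
                radiographLandmarks("extension", list(c4e, c5), "right"))
}

transformVertebra <- function(v, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- scale * matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)),
                      2, 2)
  m <- t(R %*% t(v$corners)) + rep(shift, each = nrow(v$corners))
  rownames(m) <- rownames(v$corners)
  vertebraLandmarks(v$level, m)
}

transformRadiograph <- function(rg, angle = 0, scale = 1, shift = c(0, 0)) {
  radiographLandmarks(rg$phase,
                      lapply(rg$vertebrae, transformVertebra,
                             angle = angle, scale = scale, shift = shift),
                      rg$facing)
}

transformExam <- function(exam, flex = list(angle = 0, scale = 1,
                                            shift = c(0, 0)),
                          ext = flex) {
  examLandmarks(exam$exam_id,
                do.call(transformRadiograph, c(list(exam$flexion), flex)),
                do.call(transformRadiograph, c(list(exam$extension), ext)),
                degeneration = exam$degeneration,
                condition = exam$condition)
}

# swap the two phases (relabel radiographs) to test antisymmetry
swapPhases <- function(exam) {
  examLandmarks(exam$exam_id,
                radiographLandmarks("flexion", exam$extension$vertebrae,
                                    exam$extension$facing),
                radiographLandmarks("extension", exam$flexion$vertebrae,
                                    exam$flexion$facing))
}

# brute-force ROC oracle: counts at every candidate cutoff
bruteRoc <- function(values, labels) {
  sv <- sort(unique(values))
  thr <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(values[labels] > t), numeric(1)),
    fpr = vapply(thr, function(t) mean(values[!labels] > t), numeric(1)))
}

# pairwise concordance AUC (Mann-Whitney with ties counted one half)
concordanceAuc <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
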