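test_that("identity transform reproduces the atlas label voxel-for-voxel", {
  set.seed(1)
  m <- random_blob_mask(c(14L, 14L, 14L), 30L)
  out <- build_and_roi(m)
  expect_identical(out, m)
})

test_that("a one-voxel translation shifts the label without changing size", {
  m <- array(FALSE, c(14L, 14L, 14L))
  m[5:8, 6:9, 5:7] <- TRUE  # interior cuboid
  tr <- diag(4)
  tr[1, 4] <- 2  # +2 mm = one voxel along x
  out <- build_and_roi(m, transform = tr)
  shifted <- array(FALSE, dim(m))
  shifted[6:9, 6:9, 5:7] <- TRUE
  expect_identical(out, shifted)
  expect_equal(sum(out), sum(m))
})

test_that("a label projected outside the grid raises a named error", {
  m <- array(FALSE, c(10L, 10L, 10L))
  m[4:6, 4:6, 4:6] <- TRUE
  tr <- diag(4)
  tr[1, 4] <- 1000
  expect_error(build_and_roi(m, transform = tr, name = "slf"), "slf")
  expect_error(build_and_roi(m, transform = matrix(0, 4, 4)), "invertible")
})

test_that("a single voxel dilated by 5 gives the 1330-voxel Chebyshev shell", {
  m <- array(FALSE, c(15L, 15L, 15L))
  m[8, 8, 8] <- TRUE
  shell <- build_not_shell(m, radius = 5)
  expect_equal(sum(shell), 11^3 - 1)
  expect_false(any(shell & m))
})

test_that("the empty mask yields an empty shell", {
  m <- array(FALSE, c(8L, 8L, 8L))
  expect_false(any(build_not_shell(m)))
})

test_that("shells are disjoint from and contained in the dilation of blobs", {
  set.seed(42)
  for (i in 1:20) {
    m <- random_blob_mask(c(16L, 16L, 16L), sample(5:40, 1))
    r <- sample(1:5, 1)
    shell <- build_not_shell(m, radius = r)
    dil <- dilate_mask(m, r)
    expect_false(any(shell & m))
    expect_true(all(dil[shell]))
    expect_identical(shell | m, dil)
  }
})

test_that("euclidean dilation stays inside the chebyshev dilation", {
  m <- array(FALSE, c(13L, 13L, 13L))
  m[7, 7, 7] <- TRUE
  r <- 3
  eu <- dilate_mask(m, r, metric = "euclidean")
  ch <- dilate_mask(m, r, metric = "chebyshev")
  expect_true(all(ch[eu]))
  expect_lt(sum(eu), sum(ch))
  # euclidean ball cardinality: voxels with |offset|^2 <= r^2
  offs <- expand.grid(-r:r, -r:r, -r:r)
  expect_equal(sum(eu), sum(rowSums(offs^2) <= r^2))
})

test_that("segmentation equals brute-force vertex membership filtering", {
  set.seed(7)
  dm <- c(16L, 16L, 16L)
  A <- vox_affine(c(2, 2, 2))
  for (rep in 1:20) {
    and_roi <- random_blob_mask(dm, sample(10:40, 1))
    shell <- build_not_shell(and_roi, radius = sample(1:3, 1))
    lines <- lapply(1:100, function(i) {
      n <- sample(2:12, 1)
      start <- runif(3, 0, 30)
      steps <- matrix(runif(3 * (n - 1), -3, 3), ncol = 3)
      pts <- rbind(start, start + apply(steps, 2, cumsum))
      pts
    })
    st <- streamline_set(lines, c(2, 2, 2), A, dm)
    tdef <- tract_definition("t", and_roi, shell)
    seg <- segment_tract(st, tdef)
    keep_oracle <- oracle_segment(st, and_roi, shell)
    expect_equal(length(seg$streamlines), sum(keep_oracle))
    expect_identical(seg$streamlines, st$streamlines[keep_oracle])
  }
})

test_that("dropping the NOT-shell never decreases retention", {
  set.seed(11)
  dm <- c(16L, 16L, 16L)
  A <- vox_affine(c(2, 2, 2))
  and_roi <- random_blob_mask(dm, 30)
  shell <- build_not_shell(and_roi, 3)
  lines <- lapply(1:80, function(i) {
    start <- runif(3, 0, 30)
    rbind(start, start + runif(3, -6, 6), start + runif(3, -12, 12))
  })
  st <- streamline_set(lines, c(2, 2, 2), A, dm)
  with_shell <- segment_tract(st, tract_definition("t", and_roi, shell))
  no_shell <- segment_tract(st, tract_definition("t", and_roi,
                                                 array(FALSE, dm)))
  expect_gte(length(no_shell), length(with_shell))
})

test_that("summaries are permutation invariant and voxel-set based", {
  dm <- c(10L, 10L, 10L)
  A <- vox_affine(c(2, 2, 2))
  vals <- array(0.7, dm)
  md <- scalar_volume(vals, "MD", array(TRUE, dm), 2)
  fa <- scalar_volume(array(0.4, dm), "FA", array(TRUE, dm), 2)
  lines <- lapply(1:10, function(i) {
    start <- c(2 * i - 1, 5, 5)
    rbind(start, start + c(2, 0, 0), start + c(4, 0, 0))
  })
  st1 <- streamline_set(lines, c(2, 2, 2), A, dm)
  st2 <- streamline_set(rev(lines), c(2, 2, 2), A, dm)
  s1 <- tract_summary(md, fa, st1, "t")
  s2 <- tract_summary(md, fa, st2, "t")
  expect_equal(s1$mean_md, 0.7)
  expect_equal(s1$mean_fa, 0.4)
  expect_equal(s1$mean_md, s2$mean_md)
  expect_equal(s1$n_voxels, s2$n_voxels)
})

test_that("tract means weight each visited voxel once", {
  dm <- c(6L, 6L, 6L)
  A <- vox_affine(c(2, 2, 2))
  vals <- array(0, dm)
  vals[2, 2, 2] <- 0.5
  vals[3, 2, 2] <- 0.9
  md <- scalar_volume(vals, "MD", array(TRUE, dm), 2)
  fa <- scalar_volume(vals, "FA", array(TRUE, dm), 2)
  # two vertices in voxel (1,1,1)0-based, one in (2,1,1): visits voxels
  # valued 0.5 and 0.9 once each
  line <- rbind(c(2, 2, 2), c(2.6, 2, 2), c(4, 2, 2))
  st <- streamline_set(list(line, line), c(2, 2, 2), A, dm)  # duplicated
  s <- tract_summary(md, fa, st, "t")
  expect_equal(s$mean_md, 0.7)
  expect_equal(s$n_voxels, 2L)
  expect_equal(s$n_streamlines, 2L)
})

test_that("an empty segmentation raises a tract-naming error", {
  dm <- c(6L, 6L, 6L)
  md <- scalar_volume(array(1, dm), "MD", array(TRUE, dm), 2)
  fa <- scalar_volume(array(0.3, dm), "FA", array(TRUE, dm), 2)
  st <- streamline_set(list(), c(2, 2, 2), vox_affine(c(2, 2, 2)), dm)
  expect_error(tract_summary(md, fa, st, "cst_left"), "cst_left")
})

test_that("overlapping AND and NOT masks are rejected", {
  m <- array(FALSE, c(8L, 8L, 8L))
  m[3:5, 3:5, 3:5] <- TRUE
  expect_error(tract_definition("t", m, m), "overlap")
})
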