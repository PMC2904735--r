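## Frozen orbit dependency counts o_i for orbits 0..72, computed from the
## anchored-containment definition (see .computeOrbitDependencies) and pinned
## here so the canonical numbering can never silently drift: catalog
## construction recomputes the table and aborts on any mismatch.
## o_0 = 1 (the edge depends only on itself, w_0 = 1); o_72 = 73 (every orbit
## embeds in the 5-clique, w_72 = 0).
.ORBIT_DEPENDENCY_COUNTS <- c(
  1L, 2L, 2L, 4L, 3L, 4L, 3L, 3L, 6L, 5L, 8L, 7L, 11L, 12L, 15L, 4L, 6L, 5L,
  4L, 5L, 6L, 6L, 4L, 4L, 9L, 7L, 9L, 12L, 10L, 6L, 10L, 12L, 10L, 9L, 11L,
  14L, 8L, 12L, 10L, 14L, 13L, 21L, 17L, 24L, 12L, 19L, 20L, 24L, 21L, 13L,
  13L, 23L, 21L, 20L, 25L, 36L, 31L, 37L, 43L, 32L, 16L, 37L, 26L, 27L, 27L,
  55L, 37L, 42L, 55L, 56L, 62L, 69L, 73L)
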