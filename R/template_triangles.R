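# Fixed triangulation of the canonical 66-point template (1-based vertex
# indices, one triangle per row), used for piecewise-affine warping of
# face crops onto the base mesh. Frozen so warps are reproducible.
pf_template_triangles <- matrix(c(
  47L, 46L, 17L,
  46L, 27L, 17L,
  3L, 32L, 50L,
  4L, 3L, 50L,
  3L, 2L, 32L,
  32L, 41L, 30L,
  22L, 23L, 28L,
  43L, 29L, 28L,
  23L, 43L, 28L,
  43L, 23L, 44L,
  29L, 43L, 30L,
  46L, 45L, 27L,
  45L, 46L, 47L,
  49L, 4L, 50L,
  4L, 49L, 5L,
  6L, 60L, 7L,
  49L, 6L, 5L,
  6L, 49L, 60L,
  59L, 8L, 7L,
  60L, 59L, 7L,
  31L, 32L, 30L,
  36L, 31L, 30L,
  36L, 15L, 54L,
  38L, 19L, 20L,
  21L, 38L, 20L,
  38L, 18L, 19L,
  2L, 42L, 32L,
  42L, 41L, 32L,
  42L, 2L, 1L,
  23L, 24L, 44L,
  45L, 24L, 25L,
  24L, 45L, 44L,
  48L, 43L, 44L,
  36L, 48L, 47L,
  48L, 36L, 30L,
  43L, 48L, 30L,
  26L, 45L, 25L,
  45L, 26L, 27L,
  15L, 14L, 54L,
  16L, 36L, 47L,
  16L, 15L, 36L,
  16L, 47L, 17L,
  32L, 51L, 50L,
  53L, 36L, 54L,
  14L, 55L, 54L,
  55L, 14L, 13L,
  39L, 21L, 22L,
  39L, 38L, 21L,
  42L, 37L, 38L,
  37L, 42L, 1L,
  18L, 37L, 1L,
  38L, 37L, 18L,
  31L, 33L, 32L,
  34L, 33L, 31L,
  33L, 51L, 32L,
  51L, 33L, 52L,
  33L, 34L, 52L,
  35L, 31L, 36L,
  35L, 34L, 31L,
  53L, 35L, 36L,
  35L, 53L, 52L,
  34L, 35L, 52L,
  12L, 55L, 13L,
  40L, 22L, 28L,
  40L, 39L, 22L,
  29L, 40L, 28L,
  39L, 40L, 41L,
  40L, 29L, 30L,
  41L, 40L, 30L,
  62L, 51L, 52L,
  61L, 62L, 66L,
  61L, 49L, 50L,
  49L, 61L, 60L,
  61L, 59L, 60L,
  61L, 66L, 59L,
  51L, 61L, 50L,
  62L, 61L, 51L,
  53L, 63L, 52L,
  63L, 62L, 52L,
  63L, 64L, 65L,
  55L, 64L, 54L,
  64L, 53L, 54L,
  64L, 63L, 53L,
  64L, 57L, 65L,
  10L, 57L, 11L,
  65L, 58L, 66L,
  66L, 58L, 59L,
  57L, 58L, 65L,
  8L, 58L, 9L,
  59L, 58L, 8L,
  58L, 10L, 9L,
  10L, 58L, 57L,
  56L, 64L, 55L,
  64L, 56L, 57L,
  12L, 56L, 55L,
  56L, 12L, 11L,
  57L, 56L, 11L,
  24L, 21L, 20L,
  24L, 20L, 25L,
  21L, 24L, 22L,
  24L, 23L, 22L,
  45L, 48L, 44L,
  48L, 45L, 47L,
  39L, 42L, 38L,
  42L, 39L, 41L,
  63L, 65L, 66L,
  62L, 63L, 66L
), ncol = 3, byrow = TRUE)
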