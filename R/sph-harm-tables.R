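# Cartesian monomial tables for the l = 6 orthonormal complex spherical
# harmonics (Condon-Shortley phase): r^6 * Y_6m = sum coef * x^a y^b z^c.
# Only m = 0..6 is stored; m < 0 follows from Y_{6,-m} = (-1)^m Conj(Y_{6m}).
# Generated once from the associated-Legendre definition; frozen here.
.Y6_TAB <- list(
  rbind(
    c(6, 0, 0, -0.3178460113381421, 0.0),
    c(4, 2, 0, -0.9535380340144264, 0.0),
    c(4, 0, 2, 5.721228204086558, 0.0),
    c(2, 4, 0, -0.9535380340144264, 0.0),
    c(2, 2, 2, 11.442456408173117, 0.0),
    c(2, 0, 4, -7.628304272115411, 0.0),
    c(0, 6, 0, -0.3178460113381421, 0.0),
    c(0, 4, 2, 5.721228204086558, 0.0),
    c(0, 2, 4, -7.628304272115411, 0.0),
    c(0, 0, 6, 1.0171072362820548, 0.0)
  ),
  rbind(
    c(5, 0, 1, -2.0598775815057038, 0.0),
    c(4, 1, 1, 0.0, -2.0598775815057038),
    c(3, 2, 1, -4.1197551630114075, 0.0),
    c(3, 0, 3, 8.239510326022815, 0.0),
    c(2, 3, 1, 0.0, -4.1197551630114075),
    c(2, 1, 3, 0.0, 8.239510326022815),
    c(1, 4, 1, -2.0598775815057038, 0.0),
    c(1, 2, 3, 8.239510326022815, 0.0),
    c(1, 0, 5, -3.295804130409126, 0.0),
    c(0, 5, 1, 0.0, -2.0598775815057038),
    c(0, 3, 3, 0.0, 8.239510326022815),
    c(0, 1, 5, 0.0, -3.295804130409126)
  ),
  rbind(
    c(6, 0, 0, 0.3256952429338579, 0.0),
    c(5, 1, 0, 0.0, 0.6513904858677158),
    c(4, 2, 0, 0.3256952429338579, 0.0),
    c(4, 0, 2, -5.211123886941726, 0.0),
    c(3, 3, 0, 0.0, 1.3027809717354315),
    c(3, 1, 2, 0.0, -10.422247773883452),
    c(2, 4, 0, -0.3256952429338579, 0.0),
    c(2, 0, 4, 5.211123886941726, 0.0),
    c(1, 5, 0, 0.0, 0.6513904858677158),
    c(1, 3, 2, 0.0, -10.422247773883452),
    c(1, 1, 4, 0.0, 10.422247773883452),
    c(0, 6, 0, -0.3256952429338579, 0.0),
    c(0, 4, 2, 5.211123886941726, 0.0),
    c(0, 2, 4, -5.211123886941726, 0.0)
  ),
  rbind(
    c(5, 0, 1, 1.9541714576031473, 0.0),
    c(4, 1, 1, 0.0, 5.862514372809442),
    c(3, 2, 1, -3.9083429152062945, 0.0),
    c(3, 0, 3, -5.211123886941726, 0.0),
    c(2, 3, 1, 0.0, 3.9083429152062945),
    c(2, 1, 3, 0.0, -15.633371660825178),
    c(1, 4, 1, -5.862514372809442, 0.0),
    c(1, 2, 3, 15.633371660825178, 0.0),
    c(0, 5, 1, 0.0, -1.9541714576031473),
    c(0, 3, 3, 0.0, 5.211123886941726)
  ),
  rbind(
    c(6, 0, 0, -0.356781262853998, 0.0),
    c(5, 1, 0, 0.0, -1.427125051415992),
    c(4, 2, 0, 1.7839063142699902, 0.0),
    c(4, 0, 2, 3.5678126285399805, 0.0),
    c(3, 1, 2, 0.0, 14.271250514159922),
    c(2, 4, 0, 1.7839063142699902, 0.0),
    c(2, 2, 2, -21.406875771239882, 0.0),
    c(1, 5, 0, 0.0, 1.427125051415992),
    c(1, 3, 2, 0.0, -14.271250514159922),
    c(0, 6, 0, -0.356781262853998, 0.0),
    c(0, 4, 2, 3.5678126285399805, 0.0)
  ),
  rbind(
    c(5, 0, 1, -1.6734524581000978, 0.0),
    c(4, 1, 1, 0.0, -8.36726229050049),
    c(3, 2, 1, 16.73452458100098, 0.0),
    c(2, 3, 1, 0.0, 16.73452458100098),
    c(1, 4, 1, -8.36726229050049, 0.0),
    c(0, 5, 1, 0.0, -1.6734524581000978)
  ),
  rbind(
    c(6, 0, 0, 0.48308411358006625, 0.0),
    c(5, 1, 0, 0.0, 2.8985046814803974),
    c(4, 2, 0, -7.246261703700993, 0.0),
    c(3, 3, 0, 0.0, -9.661682271601325),
    c(2, 4, 0, 7.246261703700993, 0.0),
    c(1, 5, 0, 0.0, 2.8985046814803974),
    c(0, 6, 0, -0.48308411358006625, 0.0)
  )
)
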