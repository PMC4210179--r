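# Default modelling experiment configuration: a >6 ha Amphibolis-like
# meadow site at 4.5 m depth, late-April clear sky, five canopy density
# treatments, nine neutral shading levels, 12 hourly diurnal intervals.
site:
  latitude: -30.3095
  longitude: 115.0072
  date: "2005-04-27"
  depth: 4.5
design:
  lai: [1.27, 1.94, 3.15, 5.00, 7.65]
  shading: [0, 10, 25, 40, 50, 60, 70, 85, 95]
  n_hours: 12
  n_snapshots: 14
  wave_modes: [low, high]
ek: [45, 50, 55]
optics:
  max_facet_area: 5.0e-5   # m^2 (~0.5 cm^2 leaf resolution)
  n_az: 16                 # azimuth samples per zenith bin
  n_gather: 32             # cosine gather rays per facet face
  zenith_bins: 18          # 5 degree bins over the downward hemisphere
  tol: 1.0e-4
  max_iters: 20
wave:
  amplitude: 0.15          # N per point mass (high mode)
  period: 4.0              # s
  drag: 0.02               # kg s^-1
  dt: 1.0e-3               # s
seed: 1
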