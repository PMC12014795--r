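{
  "type": "FeatureCollection",
  "properties": {"area_unit": "um2"},
  "features": [
    {
      "type": "Feature",
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[0, 0], [9000, 0], [9000, 7000], [0, 7000], [0, 0]]]
      },
      "properties": {
        "patient": "P01", "section": 2, "area_id": "P01_A1",
        "classification": {"name": "GS 4+3"}
      }
    },
    {
      "type": "Feature",
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[2000, 2000], [8000, 2500], [9000, 9000], [3000, 8000], [2000, 2000]],
                        [[4000, 4000], [6000, 4000], [6000, 6000], [4000, 6000], [4000, 4000]]]
      },
      "properties": {
        "patient": "P01", "section": 3, "area_id": "P01_A2",
        "classification": {"name": "GS 3+4"}
      }
    }
  ]
}
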