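{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {
        "name": "road_1"
      },
      "geometry": {
        "type": "LineString",
        "coordinates": [
          [
            4000,
            0
          ],
          [
            4500,
            12000
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "name": "road_2"
      },
      "geometry": {
        "type": "LineString",
        "coordinates": [
          [
            9000,
            0
          ],
          [
            8600,
            12000
          ]
        ]
      }
    }
  ]
}
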