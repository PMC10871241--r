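iI/8JgAEAAIAAAAAAAABWAAAAAAAAAGUAAAAAAAAB2gAAAAAAAAAAAAAAAAAAAAAAAABMAAAAAAAAAAAAAAAAAAAARMAAAAAAAAAAAAAB9wAAAAAAAAKAAAABEwAAAAAAAAAAAAACnQAAAAAAAALGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAzaP7b+2kAAAABAI9iA4AAAAEDQR7vTo8gAQPtfF6cmhqh4yoyRAAABAAAAAAQAAAAIAAAAAAAAAAIAAAAAAAAAAAEAAAJjdGcxAAAAAAAAD6BjdGcyAAAAAQAACcQAAAACAAAAAAAAAAAAAA98AAAAAAAAAAABAABwAAAAAAAAACJAwrm/AAAAIgAAADA/nV8tAAAAMAAAAGJBDDrEAAAAYgAAAGdBBsacAAAAZwAAAHU+7LzUAAAAdQAAAJdA4j7xAAAAlwAAAJxAqyIVAAAAuAAAAL5BF0XuAAAAvgAAAN5BEey/AAAA3gAAAP1AkenDAAAA/QAAAQ1A9PdwAAABDQAAATxAoZ1AAAABPAAAAV9AAaGLAAABXwAAAYFA5XwBAAABgQAAAY9A9cjdAAABjwAAAapA4gpoAAABqgAAAdw/9UdmAAAB/QAAAi9APqfnAAACLwAAAkhAUBWCAAACSAAAAm1AtwAaAAACbQAAAoBBDTLaAAACvQAAAuhBDFYoAAAC6AAAAwBAdvIUAAADAAAAAzJA7BZMAAADNgAAA2BA/tJ7AAADYAAAA3tA57tPAAADewAAA5hAdq5CAAADmAAAA6xAPtFFAAADrAAAA7M/EyBLAAADswAAA81A15TtAAADzQAAA+g//W3/AAAD6AAAA/pAyAjXAAAD+gAABCI/sN/BAAAEIgAABDRAbsUvAAAEbAAABIhASQR6AAAEiAAABKJBAm35AAAE6wAABRNAa7k9AAAFEwAABR9AjK+mAAAFHwAABThAjH+iAAAFOAAABVVAwJXGAAAFVQAABW9AgUAOAAAFbwAABYxBGVS3AAAF3gAABgJBG1KoAAAGAgAABhdBElMRAAAGFwAABkI/VCgdAAAGQgAABnFAmJhXAAAGcQAABnpAWQvsAAAGegAABohA13/dAAAGiAAABqNAy6zuAAAGowAABrZBCXwIAAAGtgAABtBBF7m7AAAG0AAABu9At6tiAAAG7wAABv5Aq0k+AAAG/gAAByRBFqvOAAAHLwAABzpBDsbeAAAHOgAAB19Ag0xMAAAHXwAAB3A/ABQnAAAHwAAAB9hA+QvSAAAH2AAAB/5BFCdhAAAH/gAACBhAcZXeAAAIGAAACCxAHL/bAAAILAAACDw/YFkSAAAIPAAACEpAek83AAAISgAACFo/6a26AAAIWgAACHg/qworAAAIqQAACM5AJMa5AAAIzgAACNdAsQoAAAAI1wAACPM/vYdXAAAI8wAACR9BGhBBAAAJHwAACURBFx+oAAAJrgAACcFBHsQHAAAJ9gAACgBA4fzFAAAKAAAACh8/tDJAAAAKHwAACko9t/bSAAAKVwAACnNA2623AAAKcwAACpdA2f1lAAAKpAAACr9BEs0/AAAKvwAACtRAgrHeAAAK1AAACwVAhy48AAALFgAAC0VAq/FDAAALRQAAC1NAhF3rAAAL0wAADAM/efhnAAAMAwAADDBAc18NAAAMMAAADFU//XDUAAAMVQAADHFA6AH8AAAMcQAADIw94XcVAAAMjAAADJpBEwRqAAAMrwAADLhBEAleAAAMvwAADNlA8VRJAAAM2QAADOxBGE64AAAM7AAADRRAyDAYAAANNQAADWNA0ed3AAANYwAADXdAdBSVAAANdwAADaE/J/NPAAANoQAADbBA3RT2AAANsAAADdg/oy3qAAAN2AAADfZAOnGgAAAN9gAADg5Ayk+JAAAODgAADjlAeZ2IAAAOOQAADks/NEopAAAOSwAADmVBCivyAAAOZQAADo1AdoWQAAAOjQAADpVA1qSsAAAOlQAADqw+WQzWAAAOrAAADrVAvnkkAAAOtQAADsBAMMtaAAAOwAAADs9Af3D0AAAOzwAADuA/uqTNAAAO4AAADvJBA9pjAAAPHgAADzQ/s7mDAAAPNAAAD09BEXKWAAAPTwAAD3xBD/zsAAAAAQAAAAAAAAFRAAAAAAAAAAABAAAIAAAAAAAAACc/9jUBAAAAJwAAAFdAqlU4AAAAVwAAAGtApxR1AAAAawAAAJU/zTrQAAAA+AAAAQNApkLuAAABAwAAAQ1AD66oAAABDQAAATNANCrtAAABMwAAAVFAoS4WJGis4AAAAQAAAAAAAAAAAgAAAAAAAAAAAAAAAQAAAVEAAAAAAAAHaAAABAAAAAAAAQAAAgAAAAAAAAAAAAAAAAAAD3wAAAAAAAABmAAAAAAAAAVYAAAAAQAAAAAAAAABAAABUQAAAAAAAAbwAAAAAAAAAHgAAAARAAAAAAAAAAAAAAETAAAA9z7svNRBF0XuRMqYR0Y/egAAAAAAAAABEwAAAiYAAADyP/VHZkD1yN1Egb+2RbDUVQAAAAAAAAImAAADOQAAANJAPqfnQQ0y2kSovK1GFiwjAAAAAAAAAzkAAARMAAAA+z8TIEtA/tJ7RI8irEXVAL8AAAAAAAAETAAABV8AAACqQEkEekECbflETipxRYvQIAAAAAAAAAVfAAAGcgAAAME/VCgdQRtSqESPZuhGD3xCAAAAAAAABnIAAAeFAAAA8z8AFCdBF7m7RMUz5EY5tkAAAAAAAAAHhQAACJgAAAC4P2BZEkEUJ2FETfaORaz80AAAAAAAAAiYAAAJqwAAAJs/vYdXQRoQQURv6k1F+NRAAAAAAAAACasAAAq+AAAAwT239tJBHsQHRHWq1kXt0fwAAAAAAAAKvgAAC9EAAACEQIKx3kESzT9EGRjzRTWWdwAAAAAAAAvRAAAM5AAAAPU94XcVQRhOuER765xF0WTyAAAAAAAADOQAAA33AAAA8j8n809BGE64RHUTH0WwsRAAAAAAAAAN9wAADwoAAAD7PlkM1kEKK/JEhvxsRcdAswAAAAAAAA8KAAAPoAAAAF4/s7mDQRFylkQqUyZFuPemAAAAAQAAAAAAAAETAAAAsD/NOtBAqlU4RBWxmEUfhjMAAAABAAABEwAAAiYAAAA+QDQq7UChLhZDcTCrRH2s0iRorOAAAAEAAAAAAAAAAAIAAAAAAAAAAAAAAAEAAAImAAAAAAAACgAAAAQAAAAAAAEAAAIAAAAAAAAAAAAAAAAAAA+gAAAAAAAAB+AAAAAAAAAB4AAAAAEAAAAAAAAAAQAAAiYAAAAAAAAJwAAAAAAAAABAAAAABQAAAAAAAAAAAAAETAAAA7Y+7LzUQRdF7kWhDdVHBiQrAAAAAAAABEwAAAiYAAADFj8AFCdBG1KoRYiq00byzH0AAAAAAAAImAAADOQAAALVPbf20kEexAdFXqZsRsS1mgAAAAAAAAzkAAAPoAAAAks+WQzWQRhOuEUrV8dGjDpaAAAAAQAAAAAAAARMAAAA7j/NOtBAqlU4RFH9w0Ve8WckaKzgAAABAAAAAAAAAAACAAAAAAAAAAAAAAABAAAETAAAAAAAAAsYAAAEAAAAAAABAAACAAAAAAAAAAAAAAAAAAAPoAAAAAAAAAp4AAAAAAAAAIAAAAABAAAAAAAAAAEAAARMAAAAAAAACvgAAAAAAAAAIIiP/CY=
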