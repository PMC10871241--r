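6/KJhwQAAQCTAgAAAAAAAM8CAAAAAAAAWQYAAAAAAAAGAAYAMAEAAAAAAABrAgAAAAAAAEUEAAAAAAAAAAAAAGYLAAAAAAAAzQYAAAAAAAAmBwAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAHRhYmxlIGJlZDYKIkJyb3dzZXIgRXh0ZW5zaWJsZSBEYXRhIgooCiAgICBzdHJpbmcgY2hyb20gOwkiUmVmZXJlbmNlIHNlcXVlbmNlIGNocm9tb3NvbWUgb3Igc2NhZmZvbGQiCiAgICB1aW50IGNocm9tU3RhcnQgOwkiU3RhcnQgcG9zaXRpb24gaW4gY2hyb21vc29tZSIKICAgIHVpbnQgY2hyb21FbmQgOwkiRW5kIHBvc2l0aW9uIGluIGNocm9tb3NvbWUiCiAgICBzdHJpbmcgbmFtZSA7CSJOYW1lIG9mIGl0ZW0iCiAgICB1aW50IHNjb3JlIDsJIlNjb3JlICgwLTEwMDApIgogICAgY2hhclsxXSBzdHJhbmQgOwkiKyBvciAtIGZvciBzdHJhbmQiCikKALMXAAAAAAAAAAAAAAAA8D8AAAAAAAAkQAAAAACAytZAAAAAAED5+0CRjMp4AAEAAAQAAAAIAAAAAgAAAAAAAAAAAAAAAAAAAAEAAgBjdGcxAAAAAKAPAABjdGcyAQAAAMQJAABQAAAAeJxFk01LVlEUhY9f5S5N4m2gQXNBsnu+zxmkiVCEIE6kEBEikiiKBoH/QZ00qAbNIqhR2kCCIOgvOCihRs7DSTixBq3eu9fbhTtZz11rn332vsYYM4d3oc+Y9Xt3njZWvE8yZf49O3gn+hU4qTHI5S74jHedwEv0RR2XELPEqCAxWHUsQ9wkiGJzVcc7iP0DCpKUlNXxAeAaa2Rx1qrjG8BVOorEkmS6C34BHNFRpeakUSsQbwy2wDbimkYdDwB+qAP5AaB1vIL4UWtYJ4ltvIHeYZIXl4qCLwAzBEFqZYkNpKwNKYjiC9t4BvCIIIl1Xh27AIuMypKcGgah7dCAvhNL3AK4fkpBlZidHuolwLw6XIOkrFH7ALMEVnKvjdsQDwgwccuoPYjbpxV4qY6OrwALBJi452A7ONEfAkxcD3sB8jHlJCnzyu8CHBKg7cBFOAFYHVZQcFFcz+f4eougYqxZa7wAeCwt8I3kzJt6C3CFAH0HFh9DzCSB6861dXiA+1rDe+kt4W9o72kIkrHsrWEI4kOCKClVBa8hPjmjIGF8nOtNiJ0RBVlC8HqoxbPG1FEFBb8Gh3EAsEJQcYe8ke+I2VOA3mLklH4CfDqnwErpLdt5fH1EhxNbuSLjo/9r4ETV8he4CHGTAJuOoL/hY6l1eJw90jsvRVEQBeDjbZSiUKAiIUL23mc/NaJVIyqJZ6FS6BAhkWh0FGglOr/gRrSi0ohO/ACFUkJY3FmKu4v57qzZc85pqapqH7/e1qraWF/e9kFKjDJetaDYh+ONEMUFrzCCo5OQxBkjE3+whmORkCV5L5N/cIBjtE2hSHFGo85xzCgEI8F6jfKI2SNYyehqwjGgtCs4sdnojAfAEjtqSYHwCXgleHG51qh5FC8IQVKs9Va3KN5xRhQfnUZ1ozhFSBINr9uP4maHQpbaOo2aBZywo0jmiBXUurQhGimZD/cI8EywmM3bPgJ8p4KTnINe6gVwzY4aUez4AlwRsLjj60iI2e1SCBKS0445wFC3QhRrrHasAloJSWziw934vRGjsvicdY8dwCmhSMQuzRmXgHsFxBRnteMGMKwzkpVYap3xDvhgBzZ3jPoGLBCweSoaNYfioCh4CdilGXUGGOAMbI7tm1ENwBMhYkbQqDvAIaPwyv9f1Bj+3UPA5v/f9DRgi1AkBH4kFsWGAj5bZyLgBwRQis7grGgkAAEAAAIAAAAAAAAAAAAAAEEAAAABAAAAvAkAAFkGAAAAAAAAAAQAAAAAAAABAAIAAAAAAEEAAAAAAAAAug4AANMCAAAAAAAA8gEAAAAAAAABAAAAfwAAAAEAAAC8CQAAxQQAAAAAAACUAQAAAAAAAAMAAAB4nGNggIA0bgYGVW4Qq8EeSDgycOi5MXAEusPkFvAzMIQww+QfODBsYHZliLjrCgC4MQiGeJxjZICAI5wMDFacIFaDPQODgiPDFlk3hodB7gAw5ATD4KxoJAABAAACAAAAAAAAAAAAAAAAAAAAAQAAAMQJAAAmBwAAAAAAAAAEAAAAAAAAAQACAAAAAAAAAAAAAAAAAKAPAADRBgAAAAAAADQAAAAAAAAAAQAAAAAAAAABAAAAxAkAAAUHAAAAAAAAIQAAAAAAAADr8omH
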